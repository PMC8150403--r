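# Synthetic inputs: fixture life tables, PHQ-9 cohort generator, and the
# individual-level microsimulation used as a Monte-Carlo oracle for the
# cohort engine.

# Gompertz-Makeham parameters of the shipped fixture tables, fitted once so
# that remaining (curtate) life expectancy at age 46 is 37 years for women
# and 33 years for men.
FIXTURE_GM <- list(
  female = list(a = 9.5544850781e-06, b = 0.105, c = 2e-4),
  male   = list(a = 2.1008698807e-05, b = 0.100, c = 5e-4)
)

#' Shipped synthetic life-table fixture
#'
#' A sex-stratified Gompertz-Makeham life table (ages 0-110) whose remaining
#' life expectancy at age 46 is about 37 years for women and 33 years for
#' men, in line with the adult life expectancy the case-study cohort
#' implies. It stands in for a national period life table so that the full
#' analysis runs without downloads; it is synthetic, not an official table.
#'
#' @param max_age Last tabulated age.
#' @return A two-sex [life_table()] with source `"synthetic"`.
#' @export
#' @examples
#' lt <- fixture_life_table()
#' life_expectancy(lt, 46, sex = "female")
fixture_life_table <- function(max_age = 110) {
  both <- dplyr::bind_rows(
    synthetic_life_table(FIXTURE_GM$female$a, FIXTURE_GM$female$b, FIXTURE_GM$female$c,
                         max_age = max_age, sex = "female"),
    synthetic_life_table(FIXTURE_GM$male$a, FIXTURE_GM$male$b, FIXTURE_GM$male$c,
                         max_age = max_age, sex = "male")
  )
  life_table(both$age, both$qx, both$sex, source = "synthetic")
}

#' Specification for a synthetic PHQ-9 cohort
#'
#' Describes the joint distribution of a trial-like cohort of paired
#' baseline/post PHQ-9 scores. Baseline scores all classify as depression
#' (the inclusion criterion); their severity category follows
#' `severity_dist` with scores uniform inside the category's range. Each
#' non-missing post score falls below 10 (remission) with probability
#' `theta` and is uniform within the resulting state's score range.
#'
#' @param n Number of participants.
#' @param female_fraction Share of women.
#' @param severity_dist Named probabilities over `mild`, `moderate`,
#'   `severe`; must sum to 1.
#' @param theta True remission probability among participants with a post
#'   score.
#' @param p_missing_post Probability that the post score is missing.
#' @param p_completer Probability of the completer flag (independent of the
#'   outcome given non-missingness).
#'
#' @return A list of class `cohort_generator_spec`.
#' @export
cohort_generator_spec <- function(n = 229, female_fraction = 0.681,
                                  severity_dist = c(mild = 0.50, moderate = 0.35, severe = 0.15),
                                  theta = 0.4853,
                                  p_missing_post = 1 / 229,
                                  p_completer = 147 / 229) {
  problems <- character()
  if (n < 1) problems <- c(problems, "n must be at least 1")
  if (!all(c("mild", "moderate", "severe") %in% names(severity_dist)) ||
      abs(sum(severity_dist) - 1) > 1e-9 || any(severity_dist < 0)) {
    problems <- c(problems, "severity_dist must be a distribution over mild/moderate/severe")
  }
  for (p in c(female_fraction = female_fraction, theta = theta,
              p_missing_post = p_missing_post, p_completer = p_completer)) {
    if (p < 0 || p > 1) problems <- c(problems, "probabilities must lie in [0, 1]")
  }
  if (length(problems) > 0) {
    stop(paste0("cohort_generator_spec: ", paste(unique(problems), collapse = "; ")),
         call. = FALSE)
  }
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 severity_dist = severity_dist[c("mild", "moderate", "severe")],
                 theta = theta, p_missing_post = p_missing_post,
                 p_completer = p_completer),
            class = "cohort_generator_spec")
}

#' Generate a synthetic PHQ-9 cohort
#'
#' @param spec A [cohort_generator_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A tibble of PHQ-9 records: `id`, `sex`, `baseline`, `post`
#'   (`NA` = missing), `completer`.
#' @export
#' @examples
#' generate_cohort(cohort_generator_spec(n = 10), seed = 1)
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_generator_spec"))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    n <- spec$n
    sev <- sample(names(spec$severity_dist), n, replace = TRUE, prob = spec$severity_dist)
    lo <- c(mild = 10, moderate = 15, severe = 20)[sev]
    hi <- c(mild = 14, moderate = 19, severe = 27)[sev]
    baseline <- lo + floor(stats::runif(n) * (hi - lo + 1))
    missing_post <- stats::runif(n) < spec$p_missing_post
    remit <- stats::runif(n) < spec$theta
    post <- ifelse(remit, floor(stats::runif(n) * 10), 10 + floor(stats::runif(n) * 18))
    post[missing_post] <- NA_integer_
    tibble::tibble(
      id = seq_len(n),
      sex = ifelse(stats::runif(n) < spec$female_fraction, "female", "male"),
      baseline = as.integer(baseline),
      post = as.integer(post),
      completer = stats::runif(n) < spec$p_completer
    )
  })
}

#' Individual-level microsimulation of the Markov model
#'
#' Walks `n` simulated individuals through the same age-dependent transition
#' matrices the cohort engine uses, by categorical sampling, and reports
#' mean occupancy per cycle and mean lifetime (discounted and nondiscounted)
#' QALYs and costs with Monte-Carlo standard errors. The cohort model's
#' occupancy fractions and accumulated rewards are the exact expectations of
#' these sample means, which makes the microsimulation an independent check
#' of [run_cohort()] and [accumulate_outcomes()].
#'
#' Sex is drawn per individual from the configured female fraction; rewards
#' accrue on end-of-cycle state, mirroring the cohort engine's convention.
#'
#' @param arm An [arm_spec()].
#' @param config A [model_config()].
#' @param table A [life_table()].
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#'
#' @return A list with `occupancy` (tibble: `cycle`, `remission`,
#'   `depression`, `dead`), `summary` (tibble of lifetime quantities with
#'   `mean`, `se`), and `n`.
#' @export
microsimulate <- function(arm, config, table, n = 10000, seed = 1) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_cyc <- config$n_cycles
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  sexes <- unique(table$sex)
  if (length(sexes) == 1) sex <- rep(sexes, n)
  # state codes: 1 remission, 2 depression, 3 dead
  state <- sample(1:3, n, replace = TRUE, prob = config$init)
  occ <- matrix(0, n_cyc + 1, 3)
  occ[1, ] <- tabulate(state, 3) / n
  qaly_u <- c(arm$u_remission, arm$u_depression, 0)
  hc_u <- c(arm$cost_healthcare[["remission"]], arm$cost_healthcare[["depression"]], 0)
  so_u <- c(arm$cost_societal[["remission"]], arm$cost_societal[["depression"]], 0)
  alive_u <- c(1, 1, 0)

  qalys_nd <- numeric(n); qalys_d <- numeric(n)
  cost_hc_nd <- rep(arm$cost_oneoff, n); cost_hc_d <- rep(arm$cost_oneoff, n)
  cost_so_nd <- rep(arm$cost_oneoff, n); cost_so_d <- rep(arm$cost_oneoff, n)
  ly_nd <- numeric(n)

  for (t in seq_len(n_cyc)) {
    age <- config$start_age + t - 1
    for (s in unique(sex)) {
      idx <- which(sex == s & state != 3)
      if (length(idx) == 0) next
      q_rem <- death_prob(table, age, rr = config$rr_mortality[["remission"]], sex = s)
      q_dep <- death_prob(table, age, rr = config$rr_mortality[["depression"]], sex = s)
      cur <- state[idx]
      u_death <- stats::runif(length(idx))
      dies <- u_death < ifelse(cur == 1, q_rem, q_dep)
      u_move <- stats::runif(length(idx))
      moves <- u_move < ifelse(cur == 1, arm$p_relapse, arm$p_recover)
      nxt <- ifelse(dies, 3L, ifelse(moves, ifelse(cur == 1, 2L, 1L), cur))
      state[idx] <- nxt
    }
    occ[t + 1, ] <- tabulate(state, 3) / n
    dfc <- (1 + config$discount_cost)^(-t)
    dfe <- (1 + config$discount_effect)^(-t)
    q_t <- qaly_u[state]
    hc_t <- hc_u[state] + arm$cost_recurring * alive_u[state]
    so_t <- hc_t + so_u[state]
    qalys_nd <- qalys_nd + q_t; qalys_d <- qalys_d + q_t * dfe
    cost_hc_nd <- cost_hc_nd + hc_t; cost_hc_d <- cost_hc_d + hc_t * dfc
    cost_so_nd <- cost_so_nd + so_t; cost_so_d <- cost_so_d + so_t * dfc
    ly_nd <- ly_nd + alive_u[state]
  }
  summarise_q <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n))
  qs <- rbind(
    qalys_nondiscounted = summarise_q(qalys_nd),
    qalys_discounted = summarise_q(qalys_d),
    cost_healthcare_nondiscounted = summarise_q(cost_hc_nd),
    cost_healthcare_discounted = summarise_q(cost_hc_d),
    cost_societal_nondiscounted = summarise_q(cost_so_nd),
    cost_societal_discounted = summarise_q(cost_so_d),
    life_years_nondiscounted = summarise_q(ly_nd)
  )
  list(
    occupancy = tibble::tibble(cycle = 0:n_cyc, remission = occ[, 1],
                               depression = occ[, 2], dead = occ[, 3]),
    summary = tibble::tibble(quantity = rownames(qs),
                             mean = unname(qs[, "mean"]), se = unname(qs[, "se"])),
    n = n
  )
}
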
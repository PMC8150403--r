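# Three-state Markov cohort engine: remission / depression / death with
# age-dependent, relative-risk-adjusted background mortality.

STATES <- c("remission", "depression", "dead")

#' Specify one comparator arm
#'
#' Bundles the annual transition probabilities, per-state utilities, and
#' costs of one arm. State (healthcare and societal/productivity) costs are
#' usually shared across arms; the intervention arm additionally carries a
#' one-off implementation cost charged once at model start and a recurring
#' per-patient annual delivery cost accrued for every alive person-year.
#'
#' @param name Arm label.
#' @param p_recover Annual probability of depression to remission.
#' @param p_relapse Annual probability of remission to depression.
#' @param u_remission,u_depression QALY weights per year in \[0, 1\].
#' @param cost_oneoff One-off cost, EUR per patient, charged at model start.
#' @param cost_recurring Recurring cost, EUR per patient per alive year.
#' @param cost_healthcare Named vector `c(remission = , depression = )`,
#'   EUR per patient per year of healthcare resource use.
#' @param cost_societal Named vector `c(remission = , depression = )`,
#'   EUR per patient per year of productivity losses (the societal add-on).
#'
#' @return An object of class `arm_spec`.
#' @export
#' @examples
#' arm_spec("intervention", p_recover = 0.4853, p_relapse = 0,
#'          u_remission = 0.665, u_depression = 0.529,
#'          cost_oneoff = 395.26, cost_recurring = 2439)
arm_spec <- function(name,
                     p_recover, p_relapse,
                     u_remission, u_depression,
                     cost_oneoff = 0, cost_recurring = 0,
                     cost_healthcare = c(remission = 0, depression = 0),
                     cost_societal = c(remission = 0, depression = 0)) {
  probs <- c(p_recover = p_recover, p_relapse = p_relapse)
  utils_ <- c(u_remission = u_remission, u_depression = u_depression)
  costs <- c(cost_oneoff, cost_recurring, cost_healthcare, cost_societal)
  problems <- character()
  if (any(probs < 0 | probs > 1)) {
    problems <- c(problems, "transition probabilities must lie in [0, 1]")
  }
  if (any(utils_ < 0 | utils_ > 1)) {
    problems <- c(problems, "utilities must lie in [0, 1]")
  }
  if (any(costs < 0)) problems <- c(problems, "costs must be nonnegative")
  for (nm in c("cost_healthcare", "cost_societal")) {
    v <- get(nm)
    if (!all(c("remission", "depression") %in% names(v))) {
      problems <- c(problems, sprintf("%s must name 'remission' and 'depression'", nm))
    }
  }
  if (length(problems) > 0) {
    stop(paste0("arm_spec '", name, "': ", paste(problems, collapse = "; ")), call. = FALSE)
  }
  structure(
    list(name = name, p_recover = p_recover, p_relapse = p_relapse,
         u_remission = u_remission, u_depression = u_depression,
         cost_oneoff = cost_oneoff, cost_recurring = cost_recurring,
         cost_healthcare = cost_healthcare[c("remission", "depression")],
         cost_societal = cost_societal[c("remission", "depression")]),
    class = "arm_spec"
  )
}

#' @export
print.arm_spec <- function(x, ...) {
  cat(sprintf("<arm_spec '%s'>\n", x$name))
  cat(sprintf("  p_recover %.4f, p_relapse %.4f; u %.3f (rem) / %.3f (dep)\n",
              x$p_recover, x$p_relapse, x$u_remission, x$u_depression))
  cat(sprintf("  costs: one-off %.2f, recurring %.2f/yr; healthcare %s; societal %s (EUR)\n",
              x$cost_oneoff, x$cost_recurring,
              paste(x$cost_healthcare, collapse = "/"),
              paste(x$cost_societal, collapse = "/")))
  invisible(x)
}

#' Global model configuration
#'
#' @param start_age Cohort age at model start, years.
#' @param horizon_age Age at which the model stops; the number of annual
#'   cycles is `horizon_age - start_age`.
#' @param female_fraction Share of women in the cohort, in \[0, 1\].
#' @param discount_cost,discount_effect Annual discount rates (e.g. 0.03).
#' @param wtp Willingness-to-pay threshold, EUR per QALY.
#' @param rr_mortality Named relative risks of mortality per living state,
#'   `c(remission = 1, depression = 1.68)`; hazard-scale multipliers > 0.
#' @param init Initial state distribution over
#'   `c(remission, depression, dead)`; must sum to 1.
#' @param sex_mode `"stratified"` evolves one cohort per sex and aggregates
#'   occupancy by `female_fraction` (exact when only mortality differs by
#'   sex); `"mixture"` uses a single cohort with sex-mix-weighted death
#'   probabilities.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(start_age = 46, horizon_age = 100,
                         female_fraction = 0.681,
                         discount_cost = 0.03, discount_effect = 0.03,
                         wtp = 30000,
                         rr_mortality = c(remission = 1, depression = 1.68),
                         init = c(remission = 0, depression = 1, dead = 0),
                         sex_mode = c("stratified", "mixture")) {
  sex_mode <- match.arg(sex_mode)
  problems <- character()
  if (horizon_age <= start_age) problems <- c(problems, "horizon_age must exceed start_age")
  if (female_fraction < 0 || female_fraction > 1) {
    problems <- c(problems, "female_fraction must lie in [0, 1]")
  }
  if (discount_cost < 0 || discount_effect < 0) {
    problems <- c(problems, "discount rates must be nonnegative")
  }
  if (!all(c("remission", "depression") %in% names(rr_mortality))) {
    problems <- c(problems, "rr_mortality must name 'remission' and 'depression'")
  } else if (any(rr_mortality <= 0)) {
    problems <- c(problems, "rr_mortality values must be positive")
  }
  if (length(init) != 3 || abs(sum(init) - 1) > 1e-9 || any(init < 0)) {
    problems <- c(problems, "init must be a length-3 nonnegative distribution summing to 1")
  }
  if (wtp <= 0) problems <- c(problems, "wtp must be positive")
  if (length(problems) > 0) {
    stop(paste0("model_config: ", paste(problems, collapse = "; ")), call. = FALSE)
  }
  structure(
    list(start_age = start_age, horizon_age = horizon_age, cycle_length = 1,
         n_cycles = as.integer(horizon_age - start_age),
         female_fraction = female_fraction,
         discount_cost = discount_cost, discount_effect = discount_effect,
         wtp = wtp, rr_mortality = rr_mortality[c("remission", "depression")],
         init = stats::setNames(as.numeric(init), STATES), sex_mode = sex_mode),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  ages %d -> %d (%d annual cycles), female fraction %.3f (%s)\n",
              x$start_age, x$horizon_age, x$n_cycles, x$female_fraction, x$sex_mode))
  cat(sprintf("  discount: costs %.1f%%, effects %.1f%%; WTP %.0f EUR/QALY; RR(dep) %.2f\n",
              100 * x$discount_cost, 100 * x$discount_effect, x$wtp,
              x$rr_mortality[["depression"]]))
  invisible(x)
}

#' One-cycle transition matrix at a given age
#'
#' Death is resolved first within the cycle; recovery and relapse apply only
#' to survivors. Death is absorbing, so with per-state death probabilities
#' \eqn{q_s} the depression row is
#' \eqn{((1-q_{dep}) p_{rec},\; (1-q_{dep})(1-p_{rec}),\; q_{dep})} and the
#' remission row is the analogue with \eqn{p_{rel}}.
#'
#' @param arm An [arm_spec()].
#' @param age Age at the start of the cycle.
#' @param table A [life_table()].
#' @param config A [model_config()] (supplies the mortality relative risks
#'   and, in mixture mode, the female fraction).
#' @param sex Sex to evaluate (stratified mode); `NULL` in mixture mode.
#'
#' @return A 3x3 row-stochastic matrix over
#'   `c("remission", "depression", "dead")`.
#' @export
transition_matrix <- function(arm, age, table, config, sex = NULL) {
  ff <- if (is.null(sex)) config$female_fraction else NULL
  q_rem <- death_prob(table, age, rr = config$rr_mortality[["remission"]],
                      sex = sex, female_fraction = ff)
  q_dep <- death_prob(table, age, rr = config$rr_mortality[["depression"]],
                      sex = sex, female_fraction = ff)
  m <- rbind(
    c((1 - q_rem) * (1 - arm$p_relapse), (1 - q_rem) * arm$p_relapse, q_rem),
    c((1 - q_dep) * arm$p_recover, (1 - q_dep) * (1 - arm$p_recover), q_dep),
    c(0, 0, 1)
  )
  dimnames(m) <- list(STATES, STATES)
  m
}

# Evolve one cohort (single sex or mixture) and return the occupancy matrix
# with rows t = 0..n_cycles.
evolve_occupancy <- function(arm, config, table, sex = NULL) {
  n <- config$n_cycles
  occ <- matrix(0, n + 1, 3, dimnames = list(NULL, STATES))
  occ[1, ] <- config$init
  for (t in seq_len(n)) {
    P <- transition_matrix(arm, config$start_age + t - 1, table, config, sex = sex)
    occ[t + 1, ] <- occ[t, ] %*% P
  }
  occ
}

#' Evolve a cohort over the model horizon
#'
#' Runs the Markov cohort model for one arm over
#' `horizon_age - start_age` annual cycles. In stratified mode (the default)
#' one cohort per sex present in the life table is evolved and occupancy is
#' aggregated by the female fraction; in mixture mode a single cohort uses
#' sex-mix-weighted death probabilities.
#'
#' Per-cycle rewards are undiscounted and accrue on end-of-cycle occupancy
#' (no half-cycle correction): row `cycle = t` holds the occupancy after `t`
#' transitions together with the life-years, QALYs and cost components
#' attributed to cycle `t`. Row `cycle = 0` is the initial distribution and
#' carries only the one-off cost.
#'
#' @inheritParams transition_matrix
#' @return A tibble of class `cohort_trajectory` with columns `cycle`, `age`,
#'   `remission`, `depression`, `dead`, `life_years`, `qalys`,
#'   `cost_intervention`, `cost_healthcare`, `cost_societal` (the
#'   productivity-loss add-on), and attributes `arm` and `config`.
#' @export
run_cohort <- function(arm, config, table) {
  n <- config$n_cycles
  ages_needed <- config$start_age + 0:(n - 1)
  for (s in unique(table$sex)) {
    have <- table$age[table$sex == s]
    if (min(have) > config$start_age) {
      stop(sprintf("run_cohort: life table for sex '%s' does not cover the start age", s),
           call. = FALSE)
    }
  }
  if (config$sex_mode == "stratified") {
    sexes <- unique(table$sex)
    if (length(sexes) == 1) {
      occ <- evolve_occupancy(arm, config, table, sex = sexes)
    } else {
      if (!all(c("female", "male") %in% sexes)) {
        stop("run_cohort: stratified mode needs 'female' and 'male' tables (or a single sex)",
             call. = FALSE)
      }
      occ <- config$female_fraction * evolve_occupancy(arm, config, table, sex = "female") +
        (1 - config$female_fraction) * evolve_occupancy(arm, config, table, sex = "male")
    }
  } else {
    occ <- evolve_occupancy(arm, config, table, sex = NULL)
  }
  alive <- occ[, "remission"] + occ[, "depression"]
  reward_on <- c(0, rep(1, n))  # end-of-cycle accrual: nothing at cycle 0
  traj <- tibble::tibble(
    cycle = 0:n,
    age = config$start_age + 0:n,
    remission = occ[, "remission"],
    depression = occ[, "depression"],
    dead = occ[, "dead"],
    life_years = alive * reward_on,
    qalys = (occ[, "remission"] * arm$u_remission +
               occ[, "depression"] * arm$u_depression) * reward_on,
    cost_intervention = arm$cost_recurring * alive * reward_on +
      c(arm$cost_oneoff, rep(0, n)),
    cost_healthcare = (occ[, "remission"] * arm$cost_healthcare[["remission"]] +
                         occ[, "depression"] * arm$cost_healthcare[["depression"]]) * reward_on,
    cost_societal = (occ[, "remission"] * arm$cost_societal[["remission"]] +
                       occ[, "depression"] * arm$cost_societal[["depression"]]) * reward_on
  )
  tibble::new_tibble(traj, class = "cohort_trajectory", arm = arm, config = config)
}
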
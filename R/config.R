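# Structured configuration, the shipped case-study config, the base-case
# driver, and run manifests.

CONFIG_TOP_KEYS <- c("model", "arms", "state_costs", "life_table", "sweeps", "generator")

#' Load and validate a model configuration file
#'
#' Reads a YAML configuration holding the full analysis setup: the global
#' model block (ages, discount rates, WTP, female fraction, mortality
#' relative risks), two arms (`control`, `intervention`) with transition
#' probabilities, utilities and intervention costs, the shared per-state
#' healthcare and societal (productivity) costs, life-table synthesis
#' parameters, sweep settings, and the synthetic-cohort generator settings.
#' Unknown keys are rejected by name; all invariant violations are reported
#' together rather than one at a time.
#'
#' The shipped case-study configuration is available via
#' `system.file("extdata", "superat.yaml", package = "icbtcea")`.
#'
#' @param path Path to a YAML configuration.
#' @return A list with elements `config` ([model_config()]), `control` and
#'   `intervention` ([arm_spec()]s), `life_table_params`, `sweeps`,
#'   `generator`, and `path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_TOP_KEYS)
  if (length(unknown) > 0) {
    stop(sprintf("config: unknown key '%s'", unknown[1]), call. = FALSE)
  }
  problems <- character()
  need <- function(block, keys, where) {
    miss <- setdiff(keys, names(block))
    if (length(miss) > 0) {
      problems <<- c(problems, sprintf("%s: missing key(s) %s", where,
                                       paste(sQuote(miss), collapse = ", ")))
      FALSE
    } else TRUE
  }
  check_range <- function(x, lo, hi, what) {
    if (!is.numeric(x) || x < lo || x > hi) {
      problems <<- c(problems, sprintf("%s must lie in [%g, %g] (got %s)",
                                       what, lo, hi, format(x)))
    }
  }
  m <- raw$model
  need(m, c("start_age", "horizon_age", "female_fraction", "discount_cost",
            "discount_effect", "wtp", "rr_mortality"), "model")
  arms_raw <- raw$arms
  need(arms_raw, c("control", "intervention"), "arms")
  sc <- raw$state_costs
  need(sc, c("healthcare", "societal"), "state_costs")
  for (arm_name in intersect(c("control", "intervention"), names(arms_raw))) {
    a <- arms_raw[[arm_name]]
    if (need(a, c("p_recover", "p_relapse", "u_remission", "u_depression"),
             paste0("arms$", arm_name))) {
      check_range(a$p_recover, 0, 1, paste0("arms$", arm_name, "$p_recover"))
      check_range(a$p_relapse, 0, 1, paste0("arms$", arm_name, "$p_relapse"))
      check_range(a$u_remission, 0, 1, paste0("arms$", arm_name, "$u_remission"))
      check_range(a$u_depression, 0, 1, paste0("arms$", arm_name, "$u_depression"))
    }
  }
  if (length(problems) > 0) {
    stop(paste0("config validation failed:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  cfg <- model_config(
    start_age = m$start_age, horizon_age = m$horizon_age,
    female_fraction = m$female_fraction,
    discount_cost = m$discount_cost, discount_effect = m$discount_effect,
    wtp = m$wtp,
    rr_mortality = unlist(m$rr_mortality)
  )
  mk_arm <- function(nm) {
    a <- arms_raw[[nm]]
    arm_spec(nm,
             p_recover = a$p_recover, p_relapse = a$p_relapse,
             u_remission = a$u_remission, u_depression = a$u_depression,
             cost_oneoff = a$cost_oneoff %||% 0,
             cost_recurring = a$cost_recurring %||% 0,
             cost_healthcare = unlist(sc$healthcare),
             cost_societal = unlist(sc$societal))
  }
  list(config = cfg,
       control = mk_arm("control"),
       intervention = mk_arm("intervention"),
       life_table_params = raw$life_table,
       sweeps = raw$sweeps,
       generator = raw$generator,
       path = path)
}

#' Life table described by a loaded configuration
#'
#' Builds the sex-stratified synthetic Gompertz-Makeham table from the
#' `life_table` block of a configuration (or the shipped fixture when the
#' block is absent).
#'
#' @param setup A list from [load_config()].
#' @return A [life_table()].
#' @export
config_life_table <- function(setup) {
  p <- setup$life_table_params
  if (is.null(p) || is.null(p$synthetic)) return(fixture_life_table())
  syn <- p$synthetic
  max_age <- syn$max_age %||% 110
  parts <- lapply(intersect(c("female", "male"), names(syn)), function(s) {
    g <- syn[[s]]
    synthetic_life_table(g$a, g$b, g$c, max_age = max_age, sex = s)
  })
  both <- dplyr::bind_rows(parts)
  life_table(both$age, both$qx, both$sex, source = "synthetic")
}

#' Run the base-case cost-effectiveness analysis
#'
#' Evolves both arms over the horizon, accumulates lifetime outcomes from
#' both costing perspectives with and without discounting, and compares the
#' arms at the configured willingness-to-pay threshold. Optionally writes
#' the trajectory, results and cost-effectiveness-plane CSVs plus a run
#' manifest to `out_dir`.
#'
#' @param setup A list from [load_config()], or a path to a YAML
#'   configuration.
#' @param table A [life_table()]; defaults to the one described by the
#'   configuration.
#' @param out_dir Output directory for CSVs and the manifest, or `NULL`.
#'
#' @return An object of class `cea`: list with `results` (a `ce_result`
#'   with 4 rows: 2 perspectives x discounted/nondiscounted),
#'   `trajectories`, `setup`, `table`, and `files` (written paths, if any).
#' @export
#' @examples
#' setup <- load_config(system.file("extdata", "superat.yaml", package = "icbtcea"))
#' fit <- run_base_case(setup)
#' tidy(fit)
run_base_case <- function(setup, table = NULL, out_dir = NULL) {
  if (is.character(setup)) setup <- load_config(setup)
  if (is.null(table)) table <- config_life_table(setup)
  cfg <- setup$config
  traj <- list(control = run_cohort(setup$control, cfg, table),
               intervention = run_cohort(setup$intervention, cfg, table))
  results <- dplyr::bind_rows(lapply(c("healthcare", "societal"), function(p) {
    compare_arms(accumulate_outcomes(traj$intervention, p),
                 accumulate_outcomes(traj$control, p), wtp = cfg$wtp)
  }))
  results <- tibble::new_tibble(results, class = "ce_result")
  files <- character()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop(sprintf("run_base_case: cannot create output directory '%s'", out_dir),
           call. = FALSE)
    }
    wr <- function(df, name) {
      f <- file.path(out_dir, name)
      utils::write.csv(df, f, row.names = FALSE)
      files <<- c(files, f)
    }
    for (nm in names(traj)) wr(traj[[nm]], sprintf("trajectory_%s.csv", nm))
    wr(as.data.frame(results), "results.csv")
    wr(ce_plane_points(results), "ce_plane.csv")
    manifest <- c(
      sprintf("package_version: %s", as.character(utils::packageVersion("icbtcea"))),
      sprintf("config: %s", setup$path %||% "<in-memory>"),
      sprintf("config_md5: %s",
              if (!is.null(setup$path)) unname(tools::md5sum(setup$path)) else "NA"),
      sprintf("life_table_source: %s", attr(table, "source") %||% "unknown"),
      sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      "conventions: rewards=end-of-cycle; half_cycle=none; discount=(1+r)^-t from t=1; rr_scale=hazard; oneoff=t0-undiscounted",
      "outputs:",
      paste0("  - ", basename(files))
    )
    mf <- file.path(out_dir, "manifest.txt")
    writeLines(manifest, mf)
    files <- c(files, mf)
  }
  structure(list(results = results, trajectories = traj, setup = setup,
                 table = table, files = files),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat("<cea> base-case cost-effectiveness analysis\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a base-case analysis
#'
#' @param x A `cea` object from [run_base_case()].
#' @param ... Unused.
#' @return A tibble with one row per perspective and discounting regime:
#'   incremental cost, incremental effect, ICER, dominance class and
#'   cost-effectiveness decision.
#' @export
tidy.cea <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x$results),
                "perspective", "discounting", "delta_cost", "delta_qaly",
                "icer", "dominance", "cost_effective")
}

#' One-line summary of a base-case analysis
#'
#' @param x A `cea` object.
#' @param ... Unused.
#' @return A one-row tibble: the discounted healthcare-perspective ICER,
#'   the WTP threshold, and whether every perspective/discounting variant
#'   is cost-effective at that threshold.
#' @export
glance.cea <- function(x, ...) {
  r <- x$results
  main <- r[r$perspective == "healthcare" & r$discounting == "discounted", ]
  tibble::tibble(
    icer = main$icer,
    delta_cost = main$delta_cost,
    delta_qaly = main$delta_qaly,
    wtp = main$wtp,
    cost_effective = main$cost_effective,
    all_variants_cost_effective = all(r$cost_effective),
    n_cycles = x$setup$config$n_cycles
  )
}

#' @export
autoplot.cea <- function(object, ...) autoplot(object$results, ...)
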
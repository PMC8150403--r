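# Deterministic sensitivity analyses: session-cost reduction sweep and
# effect-discount-rate sweep with willingness-to-pay intersection finding.
# Both sweeps are run nondiscounted for costs, matching the base-case
# sensitivity setting.

# Shared helper: incremental cost/effect for a (possibly modified) setup.
# Costs are always undiscounted here; effects are discounted at rate_effect.
sweep_increments <- function(control, intervention, config, table,
                             perspective, rate_effect = 0) {
  cfg <- config
  cfg$discount_cost <- 0
  cfg$discount_effect <- rate_effect
  acc <- function(arm) {
    out <- accumulate_outcomes(run_cohort(arm, cfg, table), perspective, config = cfg)
    list(cost = out$cost[out$discounting == "nondiscounted"],
         qalys = out$qalys[out$discounting == "discounted"])
  }
  ai <- acc(intervention); ac <- acc(control)
  c(delta_cost = ai$cost - ac$cost, delta_qaly = ai$qalys - ac$qalys)
}

new_sweep <- function(grid, param, perspective, wtp) {
  tibble::new_tibble(grid, class = "cea_sweep",
                     param = param, perspective = perspective, wtp = wtp)
}

#' Session-cost reduction sweep
#'
#' Recomputes the (nondiscounted) incremental results while reducing the
#' recurring intervention cost by up to `max_reduction`, emulating the lower
#' professional-to-patient ratio expected when the programme is scaled up.
#' The incremental effect is unchanged across the grid, so the ICER falls
#' affinely in the reduction fraction.
#'
#' @param control,intervention [arm_spec()]s for the two arms.
#' @param config A [model_config()]; its discount rates are ignored (the
#'   sweep is nondiscounted).
#' @param table A [life_table()].
#' @param perspective Costing perspective.
#' @param max_reduction Largest reduction as a fraction in \[0, 1).
#' @param steps Number of grid points (including both endpoints).
#'
#' @return A tibble of class `cea_sweep`: `param`, `value` (reduction
#'   fraction), `delta_cost`, `delta_qaly`, `icer`.
#' @export
sweep_session_cost <- function(control, intervention, config, table,
                               perspective = c("healthcare", "societal"),
                               max_reduction = 0.25, steps = 26) {
  perspective <- match.arg(perspective)
  if (max_reduction < 0 || max_reduction >= 1) {
    stop("sweep_session_cost: 'max_reduction' must lie in [0, 1)", call. = FALSE)
  }
  grid <- seq(0, max_reduction, length.out = steps)
  rows <- purrr::map(grid, function(x) {
    arm_x <- intervention
    arm_x$cost_recurring <- intervention$cost_recurring * (1 - x)
    d <- sweep_increments(control, arm_x, config, table, perspective)
    tibble::tibble(param = "session_cost_reduction", value = x,
                   delta_cost = d[["delta_cost"]], delta_qaly = d[["delta_qaly"]],
                   icer = d[["delta_cost"]] / d[["delta_qaly"]])
  })
  new_sweep(dplyr::bind_rows(rows), "session_cost_reduction", perspective, config$wtp)
}

#' Effect-discount-rate sweep
#'
#' Recomputes the incremental results while discounting effects at rates
#' from 0 up to `max_rate` per year, with costs left undiscounted. The
#' incremental cost is constant across the grid, so the ICER rises as the
#' rate grows.
#'
#' @inheritParams sweep_session_cost
#' @param max_rate Largest annual effect-discount rate (at most 0.10).
#'
#' @return A tibble of class `cea_sweep`: `param`, `value` (discount rate),
#'   `delta_cost`, `delta_qaly`, `icer`.
#' @export
sweep_effect_discount <- function(control, intervention, config, table,
                                  perspective = c("healthcare", "societal"),
                                  max_rate = 0.05, steps = 51) {
  perspective <- match.arg(perspective)
  if (max_rate < 0) stop("sweep_effect_discount: 'max_rate' must be nonnegative", call. = FALSE)
  if (max_rate > 0.10) stop("sweep_effect_discount: 'max_rate' must be at most 0.10", call. = FALSE)
  grid <- seq(0, max_rate, length.out = steps)
  rows <- purrr::map(grid, function(r) {
    d <- sweep_increments(control, intervention, config, table, perspective, rate_effect = r)
    tibble::tibble(param = "effect_discount_rate", value = r,
                   delta_cost = d[["delta_cost"]], delta_qaly = d[["delta_qaly"]],
                   icer = d[["delta_cost"]] / d[["delta_qaly"]])
  })
  sweep <- new_sweep(dplyr::bind_rows(rows), "effect_discount_rate", perspective, config$wtp)
  attr(sweep, "setup") <- list(control = control, intervention = intervention,
                               config = config, table = table, perspective = perspective)
  sweep
}

#' Willingness-to-pay intersection of an effect-discount sweep
#'
#' Finds where the ICER of an effect-discount sweep crosses the WTP
#' threshold. Because the incremental cost is constant over the sweep, the
#' incremental effect at the crossing is exactly `delta_cost / wtp`; the
#' corresponding discount rate is located by bisection on the monotone map
#' from rate to incremental effect, re-evaluating the cohort model until
#' `|delta_qaly - delta_cost / wtp| < tol`.
#'
#' @param sweep A `cea_sweep` from [sweep_effect_discount()].
#' @param wtp Willingness-to-pay threshold, EUR per QALY; defaults to the
#'   sweep's configured threshold.
#' @param tol Bisection tolerance on the incremental effect.
#'
#' @return A one-row tibble `rate`, `delta_qaly`, `delta_cost`, `icer`, or a
#'   zero-row tibble when the sweep's ICERs do not bracket the threshold.
#' @export
wtp_intersection <- function(sweep, wtp = attr(sweep, "wtp"), tol = 1e-6) {
  if (!identical(attr(sweep, "param"), "effect_discount_rate")) {
    stop("wtp_intersection: expects an effect-discount sweep", call. = FALSE)
  }
  empty <- tibble::tibble(rate = numeric(), delta_qaly = numeric(),
                          delta_cost = numeric(), icer = numeric())
  if (min(sweep$icer) > wtp || max(sweep$icer) < wtp) return(empty)
  setup <- attr(sweep, "setup")
  delta_cost <- sweep$delta_cost[1]
  target <- delta_cost / wtp
  dq <- function(r) {
    sweep_increments(setup$control, setup$intervention, setup$config, setup$table,
                     setup$perspective, rate_effect = r)[["delta_qaly"]]
  }
  lo <- min(sweep$value); hi <- max(sweep$value)
  # delta_qaly decreases in the rate; bisect until the effect gap closes
  repeat {
    mid <- (lo + hi) / 2
    val <- dq(mid)
    if (abs(val - target) < tol) break
    if (val > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  tibble::tibble(rate = mid, delta_qaly = val, delta_cost = delta_cost,
                 icer = delta_cost / val)
}

#' Plot a sensitivity sweep
#'
#' @param object A `cea_sweep`.
#' @param ... Unused.
#' @return A ggplot of ICER against the swept parameter with the WTP
#'   threshold as a dashed reference line.
#' @export
autoplot.cea_sweep <- function(object, ...) {
  xlab <- switch(attr(object, "param"),
                 session_cost_reduction = "Session-cost reduction (fraction)",
                 effect_discount_rate = "Effect discount rate (per year)",
                 attr(object, "param"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$icer)) +
    ggplot2::geom_hline(yintercept = attr(object, "wtp"), linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xlab, y = "ICER (EUR/QALY)",
                  title = sprintf("Deterministic sensitivity analysis (%s perspective)",
                                  attr(object, "perspective"))) +
    ggplot2::theme_minimal()
}
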
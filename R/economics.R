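# Lifetime discounted / nondiscounted costs and QALYs, incremental results,
# ICER and dominance classification, cost-effectiveness-plane data.

#' Accumulate lifetime costs and QALYs from a trajectory
#'
#' Sums the per-cycle rewards of a [run_cohort()] trajectory into lifetime
#' totals per costing perspective, discounted and nondiscounted. The reward
#' accrued at cycle `t` (t = 1..N) is discounted by \eqn{(1+r)^{-t}}; the
#' one-off cost sits at cycle 0 and is never discounted. The healthcare
#' perspective sums intervention (one-off + recurring) and healthcare state
#' costs; the societal perspective adds the productivity-loss state costs.
#'
#' @param traj A `cohort_trajectory` from [run_cohort()].
#' @param perspective `"healthcare"` or `"societal"`.
#' @param config Model configuration; defaults to the one the trajectory was
#'   produced under.
#'
#' @return A tibble with one row per discounting regime: `arm`,
#'   `perspective`, `discounting` (`"discounted"`/`"nondiscounted"`),
#'   `cost`, `qalys`, `life_years`.
#' @export
accumulate_outcomes <- function(traj, perspective = c("healthcare", "societal"),
                                config = attr(traj, "config")) {
  perspective <- match.arg(perspective)
  arm <- attr(traj, "arm")
  cost_cycle <- traj$cost_intervention + traj$cost_healthcare +
    if (perspective == "societal") traj$cost_societal else 0
  t <- traj$cycle
  # cycle-t rewards carry factor (1+r)^(-t); the one-off sits at t = 0 and is
  # therefore never discounted
  dfc <- (1 + config$discount_cost)^(-t)
  dfe <- (1 + config$discount_effect)^(-t)
  tibble::tibble(
    arm = arm$name,
    perspective = perspective,
    discounting = c("discounted", "nondiscounted"),
    cost = c(sum(cost_cycle * dfc), sum(cost_cycle)),
    qalys = c(sum(traj$qalys * dfe), sum(traj$qalys)),
    life_years = c(sum(traj$life_years * dfe), sum(traj$life_years))
  )
}

classify_dominance <- function(delta_cost, delta_qaly, eps = 1e-9) {
  if (abs(delta_cost) <= eps && abs(delta_qaly) <= eps) return("indifferent")
  if (delta_cost <= eps && delta_qaly >= -eps) return("dominant")
  if (delta_cost >= -eps && delta_qaly <= eps) return("dominated")
  if (delta_cost > 0 && delta_qaly > 0) return("NE")
  if (delta_cost < 0 && delta_qaly < 0) return("SW")
  if (delta_cost > 0 && delta_qaly < 0) return("NW")
  "SE"
}

#' Compare two accumulated arms
#'
#' Computes incremental cost and effect, the ICER, the
#' cost-effectiveness-plane dominance class, and the cost-effectiveness
#' decision at a willingness-to-pay threshold. The intervention is
#' cost-effective when it dominates, or lies in the NE quadrant with
#' ICER <= WTP, or in the SW quadrant with ICER >= WTP. The ICER is left
#' undefined (`NA`) when `|delta_qaly|` is below 1e-9.
#'
#' @param acc_intervention,acc_control Accumulations from
#'   [accumulate_outcomes()] for the two arms, produced under the same
#'   perspective and configuration.
#' @param wtp Willingness-to-pay threshold, EUR per QALY.
#'
#' @return A tibble of class `ce_result`, one row per discounting regime:
#'   arm totals, `delta_cost`, `delta_qaly`, `icer`, `dominance`,
#'   `cost_effective`, `wtp`.
#' @export
compare_arms <- function(acc_intervention, acc_control, wtp = 30000) {
  if (!identical(acc_intervention$perspective, acc_control$perspective) ||
      !identical(acc_intervention$discounting, acc_control$discounting)) {
    stop("compare_arms: accumulations differ in perspective or discounting", call. = FALSE)
  }
  res <- tibble::tibble(
    perspective = acc_intervention$perspective,
    discounting = acc_intervention$discounting,
    arm_intervention = acc_intervention$arm,
    arm_control = acc_control$arm,
    cost_intervention = acc_intervention$cost,
    cost_control = acc_control$cost,
    qalys_intervention = acc_intervention$qalys,
    qalys_control = acc_control$qalys,
    delta_cost = acc_intervention$cost - acc_control$cost,
    delta_qaly = acc_intervention$qalys - acc_control$qalys
  )
  res <- dplyr::mutate(
    res,
    icer = ifelse(abs(.data$delta_qaly) > 1e-9, .data$delta_cost / .data$delta_qaly, NA_real_),
    dominance = purrr::map2_chr(.data$delta_cost, .data$delta_qaly, classify_dominance),
    cost_effective = .data$dominance == "dominant" |
      (.data$dominance == "NE" & !is.na(.data$icer) & .data$icer <= wtp) |
      (.data$dominance == "SW" & !is.na(.data$icer) & .data$icer >= wtp),
    wtp = wtp
  )
  tibble::new_tibble(res, class = "ce_result")
}

#' Cost-effectiveness-plane points
#'
#' Extracts the `(delta_qaly, delta_cost)` points of one or more comparison
#' results together with the WTP reference line (slope = WTP through the
#' origin), ready for plotting or export.
#'
#' @param results A `ce_result` (or several, row-bound).
#' @return A tibble: `perspective`, `discounting`, `delta_qaly`,
#'   `delta_cost`, `icer`, `wtp`, and logical `below_wtp_line`.
#' @export
ce_plane_points <- function(results) {
  if (nrow(results) == 0) stop("ce_plane_points: empty result collection", call. = FALSE)
  tibble::tibble(
    perspective = results$perspective,
    discounting = results$discounting,
    delta_qaly = results$delta_qaly,
    delta_cost = results$delta_cost,
    icer = results$icer,
    wtp = results$wtp,
    below_wtp_line = results$delta_cost < results$wtp * results$delta_qaly
  )
}

#' Plot a cost-effectiveness plane
#'
#' @param object A `ce_result` (e.g. from [compare_arms()] or
#'   [run_base_case()]'s `$results`).
#' @param ... Unused.
#' @return A ggplot: incremental effect vs incremental cost with the WTP
#'   reference line through the origin.
#' @export
autoplot.ce_result <- function(object, ...) {
  pts <- ce_plane_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                                    colour = .data$perspective,
                                    shape = .data$discounting)) +
    ggplot2::geom_abline(slope = pts$wtp[1], intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Incremental effect (QALY)", y = "Incremental cost (EUR)",
                  colour = "Perspective", shape = "Discounting",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("Dashed line: WTP %.0f EUR/QALY", pts$wtp[1])) +
    ggplot2::theme_minimal()
}
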
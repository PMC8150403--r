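# PHQ-9 inputs: state/severity classification, transition-probability
# estimation, and severity-weighted utility estimation.

phq9_check_scores <- function(score, what = "score") {
  if (any(!is.finite(score) | score < 0 | score > 27 | score != floor(score))) {
    stop(sprintf("PHQ-9 %s must be an integer in [0, 27]", what), call. = FALSE)
  }
  invisible(score)
}

#' Classify a PHQ-9 score into a model health state
#'
#' Scores below 10 are remission; 10 or above is depression. These are the
#' two living states of the Markov model.
#'
#' @param score Integer PHQ-9 total score(s) in \[0, 27\].
#' @return Factor with levels `remission`, `depression`.
#' @export
#' @examples
#' classify_state(c(9, 10))
classify_state <- function(score) {
  phq9_check_scores(score)
  factor(ifelse(score < 10, "remission", "depression"),
         levels = c("remission", "depression"))
}

#' Classify a PHQ-9 score into a severity category
#'
#' Standard PHQ-9 cutoffs of 10, 15 and 20 delimit mild, moderate and severe
#' major depressive disorder; scores below 10 are subthreshold (the remission
#' state of the model).
#'
#' @inheritParams classify_state
#' @return Factor with levels `subthreshold`, `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' classify_severity(c(9, 10, 15, 20, 27))
classify_severity <- function(score) {
  phq9_check_scores(score)
  cut(score, breaks = c(-Inf, 9, 14, 19, Inf),
      labels = c("subthreshold", "mild", "moderate", "severe"))
}

#' Estimate the annual recovery (depression to remission) probability
#'
#' Estimates the probability of moving from depression at baseline to
#' remission after the intervention as a binomial proportion with a Wilson
#' 95% confidence interval. All baseline scores must classify as depression
#' (the trial's inclusion criterion). Records with a missing post score are
#' excluded from the `all_with_post` denominator; the `completers`
#' denominator additionally keeps only flagged completers.
#'
#' @param records A data frame with columns `id`, `baseline`, `post`
#'   (`NA` = missing) and logical `completer`.
#' @param denominator `"all_with_post"` or `"completers"`.
#' @param conf_level Confidence level of the Wilson interval.
#'
#' @return A one-row tibble: `n`, `n_remitted`, `estimate`, `conf_low`,
#'   `conf_high`, `n_missing_post`, `denominator`.
#' @export
#' @examples
#' recs <- tibble::tibble(id = 1:3, baseline = c(12, 15, 20),
#'                        post = c(4, 12, 8), completer = TRUE)
#' estimate_recovery_prob(recs)
estimate_recovery_prob <- function(records,
                                   denominator = c("all_with_post", "completers"),
                                   conf_level = 0.95) {
  denominator <- match.arg(denominator)
  phq9_check_scores(records$baseline, "baseline score")
  phq9_check_scores(records$post[!is.na(records$post)], "post score")
  if (any(records$baseline < 10)) {
    stop("estimate_recovery_prob: every baseline score must classify as depression (>= 10)",
         call. = FALSE)
  }
  n_missing <- sum(is.na(records$post))
  if (n_missing > 0) {
    message(sprintf("estimate_recovery_prob: excluding %d record(s) with missing post score",
                    n_missing))
  }
  kept <- dplyr::filter(records, !is.na(.data$post))
  if (denominator == "completers") kept <- dplyr::filter(kept, .data$completer)
  n <- nrow(kept)
  if (n == 0) stop("estimate_recovery_prob: empty denominator", call. = FALSE)
  x <- sum(kept$post < 10)
  # prop.test without continuity correction is the Wilson score interval; the
  # small-sample warning concerns its chi-squared statistic, not the interval
  ci <- suppressWarnings(
    stats::prop.test(x, n, correct = FALSE, conf.level = conf_level)$conf.int
  )
  tibble::tibble(
    n = n, n_remitted = x, estimate = x / n,
    conf_low = ci[1], conf_high = ci[2],
    n_missing_post = n_missing, denominator = denominator
  )
}

#' Build a severity-to-utility map
#'
#' @param utilities Named numeric vector of utilities in \[0, 1\], one per
#'   severity category (`subthreshold`, `mild`, `moderate`, `severe`); any
#'   subset may be supplied as long as it covers the categories that occur.
#' @return A tibble with columns `severity`, `utility`.
#' @export
severity_utility_map <- function(utilities) {
  levels_ok <- c("subthreshold", "mild", "moderate", "severe")
  if (is.null(names(utilities)) || !all(names(utilities) %in% levels_ok)) {
    stop("severity_utility_map: utilities must be named by severity category", call. = FALSE)
  }
  if (any(utilities < 0 | utilities > 1)) {
    stop("severity_utility_map: utilities must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(severity = factor(names(utilities), levels = levels_ok),
                 utility = as.numeric(utilities))
}

#' Severity-weighted state utility from PHQ-9 scores
#'
#' Collapses per-severity-category utilities to a single utility for one
#' model state as the category-count-weighted average over the supplied
#' scores. All scores must classify into the same model state (all < 10 or
#' all >= 10), and the map must cover every category that occurs.
#'
#' @param scores Integer PHQ-9 scores, all in one model state.
#' @param map A [severity_utility_map()].
#' @return A single utility value.
#' @export
#' @examples
#' utility_from_scores(c(12, 12, 17),
#'                     severity_utility_map(c(mild = 0.6, moderate = 0.45)))
utility_from_scores <- function(scores, map) {
  phq9_check_scores(scores)
  if (length(scores) == 0) stop("utility_from_scores: empty score set", call. = FALSE)
  states <- classify_state(scores)
  if (length(unique(states)) != 1) {
    stop("utility_from_scores: scores must all classify to the same model state", call. = FALSE)
  }
  sev <- classify_severity(scores)
  counts <- table(sev)[unique(as.character(sev))]
  missing_cat <- setdiff(names(counts), as.character(map$severity))
  if (length(missing_cat) > 0) {
    stop(sprintf("utility_from_scores: no utility mapped for category '%s'", missing_cat[1]),
         call. = FALSE)
  }
  u <- map$utility[match(names(counts), as.character(map$severity))]
  sum(u * as.numeric(counts)) / sum(counts)
}

#' Read / write PHQ-9 record files
#'
#' CSV dialect with header `id,baseline,post,completer`; an empty `post`
#' field marks a missing post-intervention score.
#'
#' @param path File path.
#' @return `read_phq9()`: a tibble with columns `id`, `baseline`, `post`,
#'   `completer`.
#' @export
read_phq9 <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("id", "baseline", "post", "completer"), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("PHQ-9 format: missing column '%s'", missing_cols[1]), call. = FALSE)
  }
  tibble::tibble(id = df$id, baseline = as.integer(df$baseline),
                 post = suppressWarnings(as.integer(df$post)),
                 completer = as.logical(df$completer))
}

#' @rdname read_phq9
#' @param records A PHQ-9 record data frame.
#' @export
write_phq9 <- function(records, path) {
  utils::write.csv(records[, c("id", "baseline", "post", "completer")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
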
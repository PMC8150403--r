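# Sex-stratified annual life tables: construction, file dialects, synthesis,
# and relative-risk-adjusted death probabilities.

#' Build a sex-stratified annual life table
#'
#' A life table holds, per sex, the annual probability of death `qx` at each
#' integer age. Ages must be contiguous (step 1) within each sex, every `qx`
#' must lie in \[0, 1\], and the final age of each sex is closed out with
#' `qx = 1` so that no cohort member survives past the table.
#'
#' @param age Integer ages, contiguous within each sex.
#' @param qx Annual death probabilities in \[0, 1\].
#' @param sex Sex label(s), recycled to the length of `age`.
#' @param source Provenance tag (a file path or `"synthetic"`).
#'
#' @return A tibble of class `life_table` with columns `sex`, `age`, `qx`
#'   and a `source` attribute.
#' @export
#' @examples
#' life_table(age = 46:48, qx = c(0.002, 0.0022, 1), sex = "female")
life_table <- function(age, qx, sex, source = "constructed") {
  tbl <- tibble::tibble(
    sex = as.character(rep(sex, length.out = length(age))),
    age = as.integer(age),
    qx  = as.numeric(qx)
  )
  tbl <- dplyr::arrange(tbl, .data$sex, .data$age)
  # forced closure: the last tabulated age is certain death
  tbl <- dplyr::group_by(tbl, .data$sex)
  tbl <- dplyr::mutate(tbl, qx = ifelse(dplyr::row_number() == dplyr::n(), 1, .data$qx))
  tbl <- dplyr::ungroup(tbl)
  out <- tibble::new_tibble(tbl, class = "life_table", source = source)
  validate_life_table(out)
  out
}

validate_life_table <- function(tbl) {
  stopifnot(all(c("sex", "age", "qx") %in% names(tbl)))
  bad <- which(!is.finite(tbl$qx) | tbl$qx < 0 | tbl$qx > 1)
  if (length(bad) > 0) {
    stop(sprintf("life table validation: qx outside [0, 1] at row %s (qx = %g)",
                 bad[1], tbl$qx[bad[1]]), call. = FALSE)
  }
  by_sex <- split(tbl, tbl$sex)
  for (s in names(by_sex)) {
    a <- by_sex[[s]]$age
    if (anyDuplicated(a) || any(diff(a) != 1L)) {
      stop(sprintf("life table validation: ages for sex '%s' must increase in steps of 1", s),
           call. = FALSE)
    }
    if (by_sex[[s]]$qx[length(a)] != 1) {
      stop(sprintf("life table validation: terminal qx for sex '%s' must equal 1", s),
           call. = FALSE)
    }
  }
  invisible(tbl)
}

#' Read a life table from disk
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`csv`}{Header `age,sex,qx`, one row per age and sex, dot decimal
#'     separator.}
#'   \item{`hmd_txt`}{A whitespace-delimited period life table in the layout
#'     used by the Human Mortality Database (columns including `Age` and `qx`;
#'     an open-ended terminal group such as `110+` is mapped to a single
#'     closing age with `qx = 1`). These files carry no sex column, so the
#'     label is supplied via `sex`.}
#' }
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"hmd_txt"`.
#' @param sex Sex label to attach when the dialect carries none (`hmd_txt`).
#' @param year For `hmd_txt` files spanning several years, which `Year` to
#'   keep; default is the first year present.
#'
#' @return A [life_table] tibble (one block per sex present in the file).
#' @export
read_life_table <- function(path, dialect = c("csv", "hmd_txt"),
                            sex = "total", year = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("life table file not found: %s", path), call. = FALSE)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(c("age", "sex", "qx"), names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("life table format: missing column '%s'", missing_cols[1]), call. = FALSE)
    }
    bad <- which(!is.finite(df$qx) | df$qx < 0 | df$qx > 1)
    if (length(bad) > 0) {
      stop(sprintf("life table validation: qx outside [0, 1] at row %d (qx = %g)",
                   bad[1], df$qx[bad[1]]), call. = FALSE)
    }
    return(life_table(df$age, df$qx, df$sex, source = path))
  }
  # hmd_txt: skip preamble lines until the header containing Age and qx
  lines <- readLines(path, warn = FALSE)
  header_at <- grep("\\bAge\\b", lines)[1]
  if (is.na(header_at)) stop("life table format: missing column 'Age'", call. = FALSE)
  header <- strsplit(trimws(lines[header_at]), "\\s+")[[1]]
  if (!"qx" %in% header) stop("life table format: missing column 'qx'", call. = FALSE)
  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "\\s+")
  fields <- fields[lengths(fields) == length(header)]
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- header
  if ("Year" %in% names(df)) {
    keep_year <- if (is.null(year)) df$Year[1] else as.character(year)
    df <- df[df$Year == keep_year, , drop = FALSE]
  }
  open_ended <- grepl("\\+$", df$Age)
  age <- as.integer(sub("\\+$", "", df$Age))
  qx <- suppressWarnings(as.numeric(df$qx))
  qx[open_ended] <- 1
  bad <- which(!is.finite(qx) | qx < 0 | qx > 1)
  if (length(bad) > 0) {
    stop(sprintf("life table validation: qx outside [0, 1] at row %d (qx = %g)",
                 bad[1], qx[bad[1]]), call. = FALSE)
  }
  life_table(age, qx, sex, source = path)
}

#' Write a life table in the CSV dialect
#'
#' Inverse of [read_life_table()] for the `csv` dialect: `age,sex,qx` with a
#' dot decimal separator.
#'
#' @param table A [life_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  validate_life_table(table)
  utils::write.csv(table[, c("age", "sex", "qx")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# One-year integrated Gompertz-Makeham hazard starting at integer age x:
# H(x) = c + (a / b) * (exp(b * (x + 1)) - exp(b * x)), reducing to c + a when b = 0.
gm_cumhaz <- function(age, a, b, c) {
  if (b > 0) c + a / b * (exp(b * (age + 1)) - exp(b * age)) else c + a
}

# Closed-form Gompertz-Makeham survivor function from age x0 to age x.
gm_survival <- function(x, x0, a, b, c) {
  if (b > 0) {
    exp(-(c * (x - x0) + a / b * (exp(b * x) - exp(b * x0))))
  } else {
    exp(-(c + a) * (x - x0))
  }
}

#' Synthesize a Gompertz-Makeham life table
#'
#' Annual death probabilities follow a Gompertz-Makeham hazard
#' \eqn{m(t) = c + a e^{b t}}: the probability of dying between exact ages
#' \eqn{x} and \eqn{x + 1} is \eqn{q(x) = 1 - \exp(-H(x))} with
#' \eqn{H(x) = \int_x^{x+1} m(t)\,dt = c + (a/b)(e^{b(x+1)} - e^{bx})}.
#' Integrating the hazard over the year (rather than evaluating it at the
#' year's start) keeps the product of annual survival probabilities exactly
#' equal to the closed-form Gompertz-Makeham survivor function. The terminal
#' age is closed with `q = 1`.
#'
#' @param a Baseline (age-dependent) hazard scale, per year; must be > 0.
#' @param b Gompertz slope, per year of age; `b = 0` gives a constant hazard.
#' @param c Makeham (age-independent) hazard constant, per year.
#' @param max_age Last tabulated age (at most 120).
#' @param sex Sex label for the table.
#'
#' @return A [life_table] covering ages `0:max_age` with source `"synthetic"`.
#' @export
#' @examples
#' lt <- synthetic_life_table(a = 2.7e-5, b = 0.095, c = 5e-4, sex = "female")
synthetic_life_table <- function(a, b = 0, c = 0, max_age = 110, sex = "total") {
  if (!is.finite(a) || a <= 0) stop("synthetic_life_table: 'a' must be positive", call. = FALSE)
  if (b < 0 || c < 0) stop("synthetic_life_table: 'b' and 'c' must be nonnegative", call. = FALSE)
  if (max_age > 120) stop("synthetic_life_table: 'max_age' must be at most 120", call. = FALSE)
  ages <- 0:max_age
  qx <- 1 - exp(-gm_cumhaz(ages, a, b, c))
  life_table(ages, qx, sex, source = "synthetic")
}

#' Annual death probability with relative-risk adjustment
#'
#' Looks up the annual death probability at `age`, applies a hazard-scale
#' relative risk, \eqn{q_{adj} = 1 - (1 - q)^{rr}}, and (optionally) mixes
#' the two sexes by the female fraction. The hazard-scale form keeps the
#' adjusted probability inside \[0, 1\] at any age, which a multiplicative
#' adjustment of `q` does not. Ages beyond the table maximum return 1.
#'
#' @param table A [life_table].
#' @param age Integer age(s) to query.
#' @param rr Relative risk of mortality (hazard multiplier), > 0.
#' @param sex Sex label to query; ignored when `female_fraction` is given.
#' @param female_fraction If not `NULL`, return the mixture
#'   `f * q_female + (1 - f) * q_male` over labels `"female"`/`"male"`.
#'
#' @return Numeric vector of adjusted death probabilities.
#' @export
#' @examples
#' lt <- synthetic_life_table(a = 2.7e-5, b = 0.095, c = 5e-4, sex = "female")
#' death_prob(lt, age = 46, rr = 1.68, sex = "female")
death_prob <- function(table, age, rr = 1, sex = NULL, female_fraction = NULL) {
  if (!is.finite(rr) || rr <= 0) stop("death_prob: 'rr' must be positive", call. = FALSE)
  lookup <- function(s) {
    sub <- table[table$sex == s, ]
    if (nrow(sub) == 0) {
      stop(sprintf("death_prob: sex '%s' not present in life table", s), call. = FALSE)
    }
    idx <- match(as.integer(age), sub$age)
    q <- sub$qx[idx]
    q[is.na(idx) & age > max(sub$age)] <- 1
    if (anyNA(q)) stop("death_prob: age below table minimum", call. = FALSE)
    q
  }
  adj <- function(q) pmin(pmax(1 - (1 - q)^rr, 0), 1)
  if (!is.null(female_fraction)) {
    stopifnot(female_fraction >= 0, female_fraction <= 1)
    return(female_fraction * adj(lookup("female")) +
             (1 - female_fraction) * adj(lookup("male")))
  }
  if (is.null(sex)) {
    sexes <- unique(table$sex)
    if (length(sexes) != 1) stop("death_prob: 'sex' required for a multi-sex table", call. = FALSE)
    sex <- sexes
  }
  adj(lookup(sex))
}

#' Remaining (curtate) life expectancy from a life table
#'
#' Sum of survivorship \eqn{\sum_k \prod_{j<k} (1 - q(x_0 + j))} from
#' `from_age` to the end of the table.
#'
#' @param table A [life_table].
#' @param from_age Starting age.
#' @param sex Sex label (required for multi-sex tables).
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(table, from_age, sex = NULL) {
  if (is.null(sex)) {
    sexes <- unique(table$sex)
    if (length(sexes) != 1) stop("life_expectancy: 'sex' required for a multi-sex table", call. = FALSE)
    sex <- sexes
  }
  sub <- table[table$sex == sex & table$age >= from_age, ]
  if (nrow(sub) == 0) stop("life_expectancy: 'from_age' beyond table", call. = FALSE)
  sum(cumprod(1 - sub$qx))
}
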
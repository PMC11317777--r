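#' Round half away from zero
#'
#' Display rounding used throughout the package for percentages and reporting
#' odds ratios. Unlike [base::round()] (banker's rounding), ties are rounded
#' away from zero, the convention of spreadsheet software and of most
#' published pharmacovigilance tables (e.g. 23/24 cases -> 95.83%).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.345, 2) # 2.35, where round() gives 2.34
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by one ulp so values like 52.295 stored as 52.29499...9 still tie up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count, display-rounded
#'
#' @param n Numerator count(s).
#' @param total Denominator.
#' @param digits Decimal places (default 2, matching published tables).
#' @return `100 * n / total`, rounded half-up.
#' @export
pct_of <- function(n, total, digits = 2) {
  round_half_up(100 * n / total, digits)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse possibly partial YYYYMMDD dates
#'
#' FAERS date fields may carry year (YYYY), month (YYYYMM) or day (YYYYMMDD)
#' precision. Returns the integer value as given plus a precision label;
#' invalid dates (month > 12, impossible day, wrong width) get `NA` value and
#' precision `"invalid"` so callers can count and skip them.
#'
#' @param x Character (or integer) vector of date strings.
#' @return A tibble with columns `value` (integer) and `prec`
#'   (`"day"`, `"month"`, `"year"`, `NA` for missing, `"invalid"`).
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  n <- nchar(x)
  value <- suppressWarnings(as.integer(x))
  prec <- rep(NA_character_, length(x))
  digits_only <- !is.na(x) & grepl("^[0-9]+$", x)

  is_year <- digits_only & n == 4L
  is_month <- digits_only & n == 6L
  is_day <- digits_only & n == 8L
  prec[is_year] <- "year"
  prec[is_month] <- "month"
  prec[is_day] <- "day"
  prec[!is.na(x) & !(is_year | is_month | is_day)] <- "invalid"

  mo <- ifelse(is_month, value %% 100L, ifelse(is_day, (value %/% 100L) %% 100L, NA))
  bad_month <- (is_month | is_day) & (mo < 1L | mo > 12L)
  # day-precision values must be real calendar dates
  bad_day <- is_day & !bad_month & is.na(as.Date(x, format = "%Y%m%d"))
  prec[bad_month | bad_day] <- "invalid"

  value[is.na(prec) | prec == "invalid"] <- NA_integer_
  tibble::tibble(value = value, prec = prec)
}

#' Convert full-precision YYYYMMDD integers to Date
#'
#' @param x Integer or character vector of YYYYMMDD values.
#' @return A `Date` vector (`NA` where the input is not a full valid date).
#' @export
faers_date <- function(x) {
  as.Date(as.character(x), format = "%Y%m%d")
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics, inclusive of
#' the extremes (R's `quantile()` type 7), the package-wide quartile
#' convention. `NA`s are dropped.
#'
#' @param x Numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`; all `NA` when `x` has no
#'   non-missing values.
#' @examples
#' median_iqr(c(7, 9, 12, 13)) # median 10.5, q1 8.5, q3 12.25
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(x, probs = c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
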
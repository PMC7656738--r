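# Shared helpers: month conversion, percent formatting, date arithmetic.

# Fixed days-per-month constant so durations are deterministic and do not
# depend on calendar-month arithmetic.
DAYS_PER_MONTH <- 30.4375

#' Convert a day span to months
#'
#' Durations are expressed as the day count divided by 30.4375 (the mean
#' length of a Gregorian month), the convention used throughout the package
#' for line-of-therapy durations and follow-up time.
#'
#' @param start,end `Date` vectors; `end` is inclusive of coverage through
#'   that day when `inclusive = TRUE`.
#' @param inclusive if `TRUE`, one day is added to the span so that a line
#'   starting and ending on the same day has a 1-day (0.03-month) duration.
#' @return numeric vector of months.
#' @export
#' @examples
#' months_between(as.Date("2010-01-01"), as.Date("2010-12-31"))
months_between <- function(start, end, inclusive = FALSE) {
  span <- as.numeric(as.Date(end) - as.Date(start)) + as.numeric(inclusive)
  span / DAYS_PER_MONTH
}

# Percent of n out of d on the 0-100 scale; NA-safe, division by zero -> NA.
pct <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)

# Round half away from zero, as tables are conventionally printed (base
# round() uses banker's rounding, which would print 12.85 -> 12.8).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stop with a configuration error naming the offending field.
config_error <- function(field, msg) {
  rlang::abort(
    sprintf("invalid configuration field `%s`: %s", field, msg),
    class = "mmlot_config_error", field = field
  )
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_error(field, "all values must be probabilities in [0, 1]")
  }
  invisible(x)
}

assert_simplex <- function(x, field, tol = 1e-9) {
  assert_prob(x, field)
  if (abs(sum(x) - 1) > tol) {
    config_error(field, sprintf("distribution must sum to 1 (got %.12f)", sum(x)))
  }
  invisible(x)
}

as_date_safe <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

# min over a possibly empty Date vector without the base warning
min_date <- function(x) {
  if (length(x) == 0) as.Date(NA) else min(x)
}
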
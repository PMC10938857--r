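# Calendar helpers. All intervals in this package are half-open [start, end):
# a follow-up window ending 2017-04-23 does not include that day.

#' Shift dates by whole calendar months, clamping to month ends
#'
#' Calendar-month arithmetic as used for the matching birthdate tolerance:
#' the same day-of-month k months away, clamped to the last day of the target
#' month (e.g. 2010-03-31 minus one month is 2010-02-28).
#'
#' @param dates a `Date` vector.
#' @param k integer number of months (scalar, may be negative).
#' @return a `Date` vector.
#' @export
add_months_clamped <- function(dates, k) {
  dates %m+% months(as.integer(k))
}

#' Shift dates by whole years, clamping Feb 29 to Feb 28
#'
#' @param dates a `Date` vector.
#' @param k integer number of years (scalar).
#' @return a `Date` vector.
#' @export
add_years_clamped <- function(dates, k) {
  dates %m+% lubridate::years(as.integer(k))
}

days_in_year <- function(year) ifelse(leap_year(year), 366L, 365L)

year_start <- function(year) as.Date(paste0(year, "-01-01"))

#' Fraction of a calendar year covered by an interval
#'
#' Overlap of the half-open interval `[start, end)` with calendar year `year`,
#' expressed as a fraction of that year's length. This is the person-year
#' weight attached to one person's presence in one calendar year.
#'
#' @param start,end `Date` vectors (recycled).
#' @param year integer vector of calendar years (recycled).
#' @return numeric vector in `[0, 1]`; `NA` where `start` or `end` is `NA`.
#' @export
year_fraction <- function(start, end, year) {
  ys <- year_start(year)
  ye <- year_start(year + 1L)
  ov <- as.numeric(pmin(end, ye) - pmax(start, ys))
  pmax(ov, 0) / as.numeric(ye - ys)
}

# Age attained on 1 July of a calendar year (integer years, floored at 0):
# the birthday counts if it falls on or before 1 July.
attained_age <- function(birth, year) {
  lt <- as.POSIXlt(birth)
  had_birthday <- (lt$mon + 1L) < 7L | ((lt$mon + 1L) == 7L & lt$mday <= 1L)
  pmax(0L, as.integer(year) - (lt$year + 1900L) - 1L + as.integer(had_birthday))
}

# 5-year band label "0-4" ... "90-94"; ages above 94 are capped into "90-94"
# (follow-up is censored at the 95th birthday).
age_band <- function(age) {
  lo <- pmin(90L, 5L * (as.integer(age) %/% 5L))
  sprintf("%d-%d", lo, lo + 4L)
}

age_band_levels <- function() sprintf("%d-%d", seq(0L, 90L, 5L), seq(4L, 94L, 5L))

# Uniform random date in [lo, hi); degenerate intervals return lo.
runif_date <- function(lo, hi) {
  span <- pmax(as.numeric(hi - lo), 0)
  lo + floor(runif(length(lo)) * span)
}
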
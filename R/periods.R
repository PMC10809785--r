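#' ISO-8601 periods and calendar-safe date arithmetic
#'
#' Surveillance frequencies are calendar periods ("every 2 years", "6 months
#' after end of treatment"), not fixed numbers of days, so the package works
#' with ISO-8601 period strings (`"P2Y"`, `"P6M"`, `"P1Y6M"`, `"P30D"`) and
#' adds them to dates month-arithmetically, clamping the day of month where
#' needed (e.g. Jan 31 + P1M = Feb 28/29).
#'
#' @param x a period string such as `"P2Y"`, or an object returned by
#'   `parse_period()`.
#' @return `parse_period()` returns a `survplan_period`, a list with integer
#'   components `years`, `months`, `days`.
#' @examples
#' parse_period("P1Y6M")
#' add_period(as.Date("2020-06-01"), "P2Y")
#' @export
parse_period <- function(x) {
  if (inherits(x, "survplan_period")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)W)?(?:([0-9]+)D)?$", x))[[1]]
  if (length(m) == 0L || m[1] == "" || x == "P")
    stop("invalid ISO-8601 period: ", x, call. = FALSE)
  num <- function(s) if (s == "") 0L else as.integer(s)
  p <- list(years = num(m[2]), months = num(m[3]),
            days = 7L * num(m[4]) + num(m[5]))
  if (p$years == 0L && p$months == 0L && p$days == 0L)
    stop("period must be strictly positive: ", x, call. = FALSE)
  structure(p, class = "survplan_period")
}

#' @export
format.survplan_period <- function(x, ...) {
  out <- "P"
  if (x$years > 0L) out <- paste0(out, x$years, "Y")
  if (x$months > 0L) out <- paste0(out, x$months, "M")
  if (x$days > 0L) out <- paste0(out, x$days, "D")
  out
}

#' @export
print.survplan_period <- function(x, ...) {
  cat("<period ", format(x), ">\n", sep = "")
  invisible(x)
}

days_in_month <- function(year, month) {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month] +
    as.integer(month == 2L & (year %% 4L == 0L & (year %% 100L != 0L | year %% 400L == 0L)))
}

add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  mon0 <- lt$year * 12L + lt$mon + n
  year <- mon0 %/% 12L + 1900L
  month <- mon0 %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(year, month))
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

#' @param date a `Date` (or ISO date string).
#' @param k integer multiplier: add the period `k` times.
#' @rdname parse_period
#' @export
add_period <- function(date, x, k = 1L) {
  p <- parse_period(x)
  date <- as.Date(date)
  add_months(date, k * (12L * p$years + p$months)) + k * p$days
}

# mean Gregorian length, used only to order frequencies ("shortest interval")
period_approx_days <- function(x) {
  p <- parse_period(x)
  p$years * 365.2425 + p$months * 30.436875 + p$days
}

#' Exact age in years between two calendar dates
#'
#' Ages are computed as elapsed days divided by 365.25, which is
#' deterministic and timezone-free.
#'
#' @param birth_date,date `Date`s or ISO date strings.
#' @return numeric years.
#' @export
age_years <- function(birth_date, date) {
  as.numeric(as.Date(date) - as.Date(birth_date)) / 365.25
}

# date at which a person reaches `age` exact years (inverse of age_years)
date_at_age <- function(birth_date, age) {
  as.Date(birth_date) + ceiling(age * 365.25)
}

as_iso_date <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) stop("invalid ", what, ": ", x, call. = FALSE)
  d
}
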
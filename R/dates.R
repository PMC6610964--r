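#' Calendar-month date arithmetic
#'
#' Follow-up windows are anniversary-anchored, so month/year offsets use
#' calendar arithmetic (same day-of-month, clamped to the end of shorter
#' months) rather than fixed 182/365-day counts. Day offsets (e.g. the
#' 90-day recurrence censor) are literal days and use plain `Date`
#' subtraction.
#'
#' @param date a `Date` vector.
#' @param n integer number of months (or years) to add; may be negative.
#' @return a `Date` vector of the same length.
#' @examples
#' add_months(as.Date("2008-01-31"), 1)  # 2008-02-29 (clamped, leap year)
#' add_years(as.Date("2007-06-15"), 2)   # 2009-06-15
#' @export
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  day <- lt$mday
  tot <- lt$year * 12L + lt$mon + as.integer(n)
  yr <- tot %/% 12L
  mo <- tot %% 12L
  last <- days_in_month(yr + 1900L, mo + 1L)
  out <- lt
  out$year <- yr
  out$mon <- mo
  out$mday <- pmin(day, last)
  as.Date(out)
}

#' @rdname add_months
#' @export
add_years <- function(date, n) add_months(date, 12L * as.integer(n))

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  d[month == 2L & leap] <- 29L
  d
}

# half-open interval membership [start, end); used for all year windows
in_window <- function(date, start, end) {
  !is.na(date) & date >= start & date < end
}

# parse with hard failure naming the offending column (CSV contract)
parse_date_col <- function(x, col) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("column '%s': unparseable ISO-8601 date at row %d ('%s')",
                 col, bad[1], x[bad[1]]), call. = FALSE)
  }
  out[!is.na(x) & x == ""] <- NA
  out
}
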
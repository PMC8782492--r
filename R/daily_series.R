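#' Calendar-dated daily series
#'
#' A `daily_series` is a data frame with columns `date` (class `Date`) and
#' `value` (numeric; `NA` marks an explicit gap), plus attributes identifying
#' the station or region, the variable measured, and its units. Dates must be
#' strictly increasing with no duplicates. Gaps are retained as `NA` and never
#' interpolated at construction; gap policy is applied downstream (see
#' [annual_mean_flow()]).
#'
#' @param dates `Date` vector (or unambiguous character), strictly increasing.
#' @param values numeric vector the same length as `dates`; `NA` = missing.
#' @param id station or region identifier.
#' @param variable `"discharge"` or `"temperature"`.
#' @param units unit string; conventionally `"m3/s"`/`"ft3/s"` for discharge
#'   and `"degC"` for temperature.
#' @return A `daily_series` data frame.
#' @examples
#' daily_series(as.Date("2015-01-01") + 0:2, c(1.2, NA, 1.4), "09253000")
#' @export
daily_series <- function(dates, values, id = "series",
                         variable = c("discharge", "temperature"),
                         units = NULL) {
  variable <- match.arg(variable)
  dates <- as.Date(dates)
  if (anyNA(dates)) gw_format_error("unparseable calendar date in 'dates'")
  if (length(dates) != length(values)) {
    gw_integrity_error("'dates' and 'values' lengths differ")
  }
  if (anyDuplicated(dates)) {
    gw_integrity_error(sprintf("duplicate date: %s",
                               as.character(dates[duplicated(dates)][1])))
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    gw_integrity_error("dates must be strictly increasing")
  }
  values <- as.numeric(values)
  values[!is.finite(values)] <- NA_real_
  if (is.null(units)) {
    units <- if (variable == "discharge") "m3/s" else "degC"
  }
  structure(
    data.frame(date = dates, value = values),
    id = id, variable = variable, units = units,
    class = c("daily_series", "data.frame")
  )
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s [%s, %s]: %d days, %s to %s, %d missing\n",
              attr(x, "id"), attr(x, "variable"), attr(x, "units"),
              nrow(x), as.character(min(x$date)), as.character(max(x$date)),
              sum(is.na(x$value))))
  invisible(x)
}

#' Day-of-year (Julian day)
#'
#' January 1 maps to 1; December 31 maps to 365, or 366 in leap years.
#'
#' @param date a `Date` vector (or unambiguous character).
#' @return integer day-of-year.
#' @examples
#' julian_day(as.Date("2008-05-16")) # 137 (leap year)
#' @export
julian_day <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) gw_format_error("unparseable calendar date")
  as.POSIXlt(date)$yday + 1L
}

series_years <- function(x) as.integer(format(x$date, "%Y"))

#' Extract one calendar year from a daily series
#'
#' @param x a [daily_series()].
#' @param year calendar year.
#' @return a `daily_series` restricted to `year` (possibly zero rows).
#' @export
year_slice <- function(x, year) {
  keep <- series_years(x) == year
  structure(
    data.frame(date = x$date[keep], value = x$value[keep]),
    id = attr(x, "id"), variable = attr(x, "variable"), units = attr(x, "units"),
    class = c("daily_series", "data.frame")
  )
}

year_length <- function(year) {
  julian_day(as.Date(sprintf("%d-12-31", year)))
}

## TRUE when the slice covers Jan 1..Dec 31 of `year` with one row per day.
complete_year <- function(x, year) {
  n <- year_length(year)
  nrow(x) == n &&
    x$date[1] == as.Date(sprintf("%d-01-01", year)) &&
    x$date[nrow(x)] == as.Date(sprintf("%d-12-31", year))
}
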
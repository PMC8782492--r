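## Snowmelt spring-pulse detection from daily hydrographs and the daily
## Dsm / Dpsm covariates built from the detected pulse days.

fill_gaps <- function(values, max_gap) {
  values <- as.numeric(values)
  if (!anyNA(values)) return(values)
  if (all(is.na(values))) gw_incomplete_year("all values missing")
  filled <- zoo::na.approx(values, maxgap = max_gap, na.rm = FALSE)
  if (anyNA(filled)) {
    gw_incomplete_year(sprintf(
      "gap longer than %d days (or at a year boundary); year excluded", max_gap))
  }
  filled
}

#' Calendar-year annual mean streamflow
#'
#' Arithmetic mean over the year after linear interpolation of gaps up to
#' `max_gap` consecutive days. Longer gaps (or gaps touching the year's ends,
#' which cannot be interpolated) raise an incomplete-year condition so the
#' year can be excluded.
#'
#' @param flows one calendar year of daily flows: a [daily_series()] slice or
#'   a numeric vector (NA = gap).
#' @param max_gap longest gap (days) to interpolate linearly; default 7.
#' @return annual mean flow.
#' @export
annual_mean_flow <- function(flows, max_gap = 7) {
  values <- if (inherits(flows, "daily_series")) flows$value else flows
  mean(fill_gaps(values, max_gap))
}

#' Spring-pulse onset day by cumulative departure
#'
#' The snowmelt spring-pulse onset is the Julian day at which the running sum
#' of daily departures from a reference mean flow,
#' `C_i = sum_{k<=i} (Q_k - reference)`, attains its minimum -- the last day
#' before sustained above-reference snowmelt flows dominate the record. Ties
#' break to the earliest day. `convention = "min_plus_one"` instead reports
#' the first rising day (minimum + 1), a convention that also appears in the
#' runoff-timing literature.
#'
#' @param flows one calendar year of daily flows (gap-filled upstream): a
#'   [daily_series()] slice or numeric vector.
#' @param reference_mean reference mean flow; by convention the same year's
#'   annual mean, or the previous year's for the lagged variant.
#' @param convention `"min"` (default) or `"min_plus_one"`.
#' @return Julian day (integer).
#' @export
spring_pulse_day <- function(flows, reference_mean,
                             convention = c("min", "min_plus_one")) {
  convention <- match.arg(convention)
  values <- if (inherits(flows, "daily_series")) flows$value else as.numeric(flows)
  if (!length(values) || all(is.na(values))) gw_incomplete_year("all values missing")
  if (anyNA(values)) gw_incomplete_year("gaps present; apply gap policy first")
  cumdep <- cumsum(values - reference_mean)
  day <- which.min(cumdep) # earliest tie: which.min returns the first minimum
  if (convention == "min_plus_one") day <- min(day + 1L, length(values))
  as.integer(day)
}

#' Daily snowmelt covariate
#'
#' Days elapsed since (negative: until) the year's spring-pulse onset:
#' `Dsm_ji = J_ji - pulse_day_j`.
#'
#' @param julian_day integer Julian day(s).
#' @param pulse_day the year's detected pulse day.
#' @return difference in days.
#' @export
dsm_covariate <- function(julian_day, pulse_day) {
  julian_day - pulse_day
}

#' Per-year spring-pulse features (current-year reference)
#'
#' For each calendar year of a multi-year flow record: the gap-filled annual
#' mean and the pulse day detected against that same year's mean. Years whose
#' gaps exceed the policy are kept with `complete = FALSE`.
#'
#' @param series multi-year discharge [daily_series()].
#' @param max_gap gap policy passed to [annual_mean_flow()].
#' @inheritParams spring_pulse_day
#' @return data frame: `station_id`, `year`, `annual_mean_flow`, `pulse_day`,
#'   `reference`, `complete`.
#' @export
pulse_features <- function(series, max_gap = 7,
                           convention = c("min", "min_plus_one")) {
  convention <- match.arg(convention)
  stopifnot(inherits(series, "daily_series"))
  yrs <- sort(unique(series_years(series)))
  rows <- lapply(yrs, function(yr) {
    out <- data.frame(station_id = attr(series, "id"), year = yr,
                      annual_mean_flow = NA_real_, pulse_day = NA_integer_,
                      reference = "current_year_mean", complete = FALSE)
    slice <- year_slice(series, yr)
    if (!complete_year(slice, yr)) return(out)
    filled <- tryCatch(fill_gaps(slice$value, max_gap),
                       gw_incomplete_year = function(e) NULL)
    if (is.null(filled)) return(out)
    out$annual_mean_flow <- mean(filled)
    out$pulse_day <- spring_pulse_day(filled, out$annual_mean_flow, convention)
    out$complete <- TRUE
    out
  })
  do.call(rbind, rows)
}

#' Per-year spring-pulse features (previous-year reference)
#'
#' The lagged variant usable for real-time forecasting: the pulse day of year
#' `j` is detected against the annual mean of year `j - 1`, which is known
#' before year `j` unfolds. Years without a complete previous year are
#' skipped with a message.
#'
#' @inheritParams pulse_features
#' @return data frame as in [pulse_features()] with
#'   `reference = "previous_year_mean"`; first year absent.
#' @export
lagged_pulse_features <- function(series, max_gap = 7,
                                  convention = c("min", "min_plus_one")) {
  convention <- match.arg(convention)
  cur <- pulse_features(series, max_gap, convention)
  rows <- list()
  for (i in seq_len(nrow(cur))) {
    yr <- cur$year[i]
    prev <- cur[cur$year == yr - 1L, ]
    if (!nrow(prev) || !prev$complete || !cur$complete[i]) {
      if (cur$complete[i]) {
        message(sprintf("year %d: no complete previous year; lagged feature skipped", yr))
      }
      next
    }
    slice <- year_slice(series, yr)
    filled <- fill_gaps(slice$value, max_gap)
    rows[[length(rows) + 1]] <- data.frame(
      station_id = attr(series, "id"), year = yr,
      annual_mean_flow = prev$annual_mean_flow,
      pulse_day = spring_pulse_day(filled, prev$annual_mean_flow, convention),
      reference = "previous_year_mean", complete = TRUE)
  }
  if (!length(rows)) {
    return(data.frame(station_id = character(), year = integer(),
                      annual_mean_flow = numeric(), pulse_day = integer(),
                      reference = character(), complete = logical()))
  }
  do.call(rbind, rows)
}

#' Correlation between current- and previous-reference pulse days
#'
#' Pearson correlation of annual pulse days computed with the current-year
#' versus previous-year reference mean, paired by year.
#'
#' @param features_current,features_lagged outputs of [pulse_features()] and
#'   [lagged_pulse_features()].
#' @return Pearson R.
#' @export
pulse_correlation <- function(features_current, features_lagged) {
  m <- merge(features_current[features_current$complete,
                              c("year", "pulse_day")],
             features_lagged[features_lagged$complete,
                             c("year", "pulse_day")],
             by = "year", suffixes = c("_current", "_lagged"))
  if (nrow(m) < 3) gw_insufficient_data("need at least 3 paired years")
  if (stats::sd(m$pulse_day_current) == 0 || stats::sd(m$pulse_day_lagged) == 0) {
    gw_domain_error("undefined correlation: a pulse-day series is constant")
  }
  stats::cor(m$pulse_day_current, m$pulse_day_lagged)
}
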
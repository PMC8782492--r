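#' Growing-degree-day base temperature from latitude
#'
#' The base temperature is a linear function of latitude,
#' `T_base = -0.25 * latitude + 13` (degrees C), so that higher-latitude
#' (colder) basins accumulate growing degree units against a lower threshold.
#'
#' @param latitude degrees north, in `[-90, 90]`.
#' @return base temperature in degrees C.
#' @examples
#' base_temperature(41) # 2.75
#' @export
base_temperature <- function(latitude) {
  if (any(latitude < -90 | latitude > 90)) {
    gw_domain_error("latitude must lie in [-90, 90]")
  }
  -0.25 * latitude + 13
}

#' Cumulative growing degree day curve for one calendar year
#'
#' Daily growing degree units are `GDU_i = T_i - t_base`, accumulated from
#' January 1. By default negative GDUs are floored at zero (standard
#' growing-degree-day practice, and required for the curve to be monotone so
#' that a sigmoid can be fitted); set `floor_at_zero = FALSE` for the literal
#' unfloored accumulation.
#'
#' @param temps a [daily_series()] of temperature covering one complete
#'   calendar year (Jan 1 to Dec 31, no gaps).
#' @param t_base base temperature in degrees C (see [base_temperature()]).
#' @param floor_at_zero floor daily GDUs at 0 (default `TRUE`).
#' @return numeric vector of cumulative GDD (degC day), one entry per day.
#' @export
gdd_series <- function(temps, t_base, floor_at_zero = TRUE) {
  stopifnot(inherits(temps, "daily_series"))
  yrs <- unique(series_years(temps))
  if (length(yrs) != 1) gw_incomplete_year("temps must cover exactly one calendar year")
  if (!complete_year(temps, yrs) || anyNA(temps$value)) {
    gw_incomplete_year(sprintf("year %d: incomplete daily temperature coverage", yrs))
  }
  gdu <- temps$value - t_base
  if (floor_at_zero) gdu <- pmax(gdu, 0)
  cumsum(gdu)
}

#' First day the cumulative GDD exceeds a threshold
#'
#' The "first day of spring": the smallest day whose cumulative GDD strictly
#' exceeds the threshold (180 degC day by default).
#'
#' @param gdd_curve cumulative GDD vector from [gdd_series()].
#' @param threshold exceedance threshold in degC day.
#' @return Julian day (integer), or `NA` when the curve never exceeds it.
#' @export
gdd180_day <- function(gdd_curve, threshold = 180) {
  idx <- which(gdd_curve > threshold)
  if (!length(idx)) return(NA_integer_)
  as.integer(idx[1])
}

#' Fit a three-parameter logistic (sigmoid) to a cumulative GDD curve
#'
#' Fits `f(t) = Asym / (1 + exp((xmid - t)/scal))` by least squares using the
#' self-starting logistic model ([stats::SSlogis()]); if self-start fails, a
#' deterministic fallback start is used: `Asym0 = 1.05 * max`, `xmid0` = first
#' day the curve reaches `Asym0/2`, `scal0` = a quarter of the 10%-to-90% rise
#' span. Non-convergence is reported via the `converged` flag rather than an
#' error, so a multi-year scan can skip bad years.
#'
#' @param gdd_curve nondecreasing cumulative GDD vector with a rise.
#' @return list with `Asym` (degC day), `xmid` (Julian day), `scal` (days),
#'   `converged` (flag); class `sigmoid_fit`.
#' @export
fit_sigmoid <- function(gdd_curve) {
  y <- as.numeric(gdd_curve)
  t <- seq_along(y)
  if (length(y) < 5 || anyNA(y)) gw_fit_error("curve too short or has gaps")
  if (max(y) <= min(y)) gw_fit_error("flat curve: no rise to fit a sigmoid to")
  dat <- data.frame(t = t, y = y)
  ## scaleOffset lets nls declare convergence on (near-)zero-residual curves
  ctrl <- stats::nls.control(maxiter = 200, scaleOffset = 1)
  fit <- tryCatch(
    stats::nls(y ~ stats::SSlogis(t, Asym, xmid, scal), data = dat, control = ctrl),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    asym0 <- 1.05 * max(y)
    xmid0 <- t[which(y >= asym0 / 2)[1]]
    rng <- min(y) + c(0.1, 0.9) * (max(y) - min(y))
    t10 <- t[which(y >= rng[1])[1]]
    t90 <- t[which(y >= rng[2])[1]]
    scal0 <- max((t90 - t10) / 4, 1)
    fit <- tryCatch(
      stats::nls(y ~ Asym / (1 + exp((xmid - t) / scal)), data = dat,
                 start = list(Asym = asym0, xmid = xmid0, scal = scal0),
                 control = ctrl),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    return(structure(list(Asym = NA_real_, xmid = NA_real_, scal = NA_real_,
                          converged = FALSE), class = "sigmoid_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(Asym = unname(cf["Asym"]), xmid = unname(cf["xmid"]),
                 scal = unname(cf["scal"]), converged = TRUE),
            class = "sigmoid_fit")
}

## logit of the smaller root of 12 p^2 - 12 p + 1 = 0; the third derivative of
## the logistic attains its maximum at s = p* (the critical points satisfy
## (1 - 2s)(12 s^2 - 12 s + 1) = 0), giving jerk = xmid + scal * logit(p*).
JERK_LOGIT <- local({
  p <- 1 / 2 - sqrt(96) / 24
  log(p / (1 - p))
})

#' Day of maximum third derivative of a fitted sigmoid ("jerk" day)
#'
#' The moment spring warm-up accelerates fastest: the argmax over days of the
#' third derivative of the fitted logistic GDD curve. For the logistic form
#' this has the closed form `xmid + scal * logit(p*)` with
#' `p* = 1/2 - sqrt(96)/24`, i.e. approximately `xmid - 2.2924 * scal`; a
#' numeric grid maximization of the analytic third derivative is available as
#' a cross-check and both agree to well under 0.01 day.
#'
#' The logistic third derivative is symmetric about `xmid`, so an equal
#' mirror peak exists at `xmid + 2.2924 * scal` on the flattening side of the
#' curve; the jerk day is the peak on the rising side, where spring warm-up
#' is accelerating, and the numeric search is restricted to that branch.
#'
#' @param params a `sigmoid_fit` from [fit_sigmoid()] (or any list with
#'   `xmid`, `scal`, and, for the numeric method, `Asym`).
#' @param method `"closed_form"` (default) or `"numeric"` (0.001-day grid over
#'   `xmid` minus `6 * scal` up to `xmid`).
#' @return Julian day (real-valued).
#' @export
jerk_day <- function(params, method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  scal <- params$scal
  if (is.na(scal) || scal <= 0) gw_domain_error("scal must be positive")
  if (method == "closed_form") {
    return(params$xmid + scal * JERK_LOGIT)
  }
  asym <- if (is.null(params$Asym) || is.na(params$Asym)) 1 else params$Asym
  t <- seq(params$xmid - 6 * scal, params$xmid, by = 0.001)
  s <- stats::plogis((t - params$xmid) / scal)
  f3 <- asym / scal^3 * s * (1 - s) * (6 * s^2 - 6 * s + 1)
  t[which.max(f3)]
}

#' Daily jerk covariate
#'
#' Days elapsed since (negative: until) the year's jerk day:
#' `JERK_ji = J_ji - jerk_day_j`.
#'
#' @param julian_day integer Julian day(s).
#' @param jerk_day the year's jerk day (real).
#' @return difference in days.
#' @export
jerk_covariate <- function(julian_day, jerk_day) {
  julian_day - jerk_day
}

#' Basin-mean temperature from grid values
#'
#' The simple arithmetic mean of the gridded temperature values falling inside
#' the basin for one day.
#'
#' @param grid_values nonempty numeric vector of grid-cell temperatures (degC).
#' @return mean temperature (degC).
#' @export
basin_mean_temperature <- function(grid_values) {
  if (!length(grid_values)) gw_domain_error("empty grid subset")
  mean(as.numeric(grid_values))
}

#' Per-year temperature phenology features
#'
#' Runs the GDD pipeline over every complete calendar year of a multi-year
#' temperature series: cumulative GDD, the GDD-180 day, the sigmoid fit, and
#' the jerk day. Incomplete years are reported with `complete = FALSE`.
#'
#' @param temps multi-year temperature [daily_series()].
#' @param latitude representative basin latitude for [base_temperature()].
#' @inheritParams gdd_series
#' @param threshold GDD exceedance threshold for [gdd180_day()].
#' @return data frame: `year`, `gdd180_day`, `Asym`, `xmid`, `scal`,
#'   `jerk_day`, `converged`, `complete`.
#' @export
annual_pheno_features <- function(temps, latitude, floor_at_zero = TRUE,
                                  threshold = 180) {
  t_base <- base_temperature(latitude)
  yrs <- sort(unique(series_years(temps)))
  rows <- lapply(yrs, function(yr) {
    slice <- year_slice(temps, yr)
    out <- data.frame(year = yr, gdd180_day = NA_integer_, Asym = NA_real_,
                      xmid = NA_real_, scal = NA_real_, jerk_day = NA_real_,
                      converged = FALSE, complete = FALSE)
    curve <- tryCatch(gdd_series(slice, t_base, floor_at_zero),
                      gw_incomplete_year = function(e) NULL)
    if (is.null(curve)) return(out)
    out$complete <- TRUE
    out$gdd180_day <- gdd180_day(curve, threshold)
    fit <- tryCatch(fit_sigmoid(curve), gw_fit_error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      out$Asym <- fit$Asym
      out$xmid <- fit$xmid
      out$scal <- fit$scal
      out$jerk_day <- jerk_day(fit)
      out$converged <- TRUE
    }
    out
  })
  do.call(rbind, rows)
}
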
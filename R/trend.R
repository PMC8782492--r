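## Nonparametric trend machinery: Kendall-Theil (Theil-Sen) slope,
## Mann-Kendall significance with tie correction, lag-1 autocorrelation check.

#' Kendall-Theil (Theil-Sen) robust line fit
#'
#' The slope is the median of all pairwise slopes
#' `(y_j - y_i)/(x_j - x_i)`, `i < j`; the intercept is
#' `median(y - slope * x)`. An even number of pairwise slopes is resolved as
#' the midpoint of the two central values (the usual sample median).
#'
#' @param x strictly increasing numeric (years), `n >= 3`.
#' @param y numeric response (Julian days).
#' @return list with `slope` and `intercept`.
#' @examples
#' theil_sen(1:3, c(1, 2, 100))$slope # 49.5
#' @export
theil_sen <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) gw_insufficient_data("need n >= 3 paired points")
  if (is.unsorted(x, strictly = TRUE)) gw_domain_error("x must be strictly increasing")
  dy <- outer(y, y, "-")
  dx <- outer(x, x, "-")
  slopes <- (dy / dx)[lower.tri(dx)] # row > col: (y_j - y_i)/(x_j - x_i), i < j
  slope <- stats::median(slopes)
  list(slope = slope, intercept = stats::median(y - slope * x))
}

#' Mann-Kendall trend test
#'
#' `S = sum_{i<j} sign(y_j - y_i)`; variance with tie correction
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of
#' size `t`; two-sided p-value from the normal approximation with continuity
#' correction, `Z = (S - sign(S)) / sqrt(Var(S))`. A fully tied series has
#' `S = 0`, `Var(S) = 0` and is reported as `p = 1`.
#'
#' @param y ordered annual values, `n >= 4`.
#' @return list with `S` (integer) and `p`.
#' @export
mann_kendall <- function(y) {
  n <- length(y)
  if (n < 4) gw_insufficient_data("need n >= 4 values")
  sgn <- sign(outer(y, y, "-")) # [j, i] = sign(y_j - y_i)
  S <- sum(sgn[lower.tri(sgn)])
  ties <- table(y)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (varS <= 0) return(list(S = as.integer(S), p = 1))
  z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  list(S = as.integer(S), p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Lag-1 sample autocorrelation with a significance flag
#'
#' Computed with [stats::acf()]; flagged when `|r1| > 1.96 / sqrt(n)` (the
#' large-sample white-noise bound).
#'
#' @param y numeric series, `n >= 5`.
#' @return list with `r1`, `flagged`, `bound`.
#' @export
lag1_autocorrelation <- function(y) {
  n <- length(y)
  if (n < 5) gw_insufficient_data("need n >= 5 values")
  if (stats::sd(y) == 0) gw_domain_error("autocorrelation undefined for a constant series")
  r1 <- drop(stats::acf(y, lag.max = 1, plot = FALSE)$acf[2])
  bound <- 1.96 / sqrt(n)
  list(r1 = r1, flagged = abs(r1) > bound, bound = bound)
}

#' Trend test for an annual series
#'
#' Combines the Kendall-Theil slope, the Mann-Kendall significance test, and
#' the lag-1 autocorrelation pre-check. A flagged autocorrelation annotates
#' the result (`lag1_flagged`); it does not suppress it. Slopes are also
#' reported per decade to match how runoff-timing trends are usually quoted.
#'
#' @param years strictly increasing integer years.
#' @param values annual values (e.g. pulse days).
#' @param alpha significance level for the `significant` flag.
#' @return one-row data frame: `n`, `slope_per_year`, `slope_per_decade`,
#'   `intercept`, `mk_S`, `mk_p`, `significant`, `lag1_autocorr`,
#'   `lag1_flagged`.
#' @export
trend_test <- function(years, values, alpha = 0.05) {
  keep <- !is.na(values)
  years <- years[keep]
  values <- values[keep]
  ts_fit <- theil_sen(years, values)
  mk <- mann_kendall(values)
  ac <- tryCatch(lag1_autocorrelation(values),
                 gw_error = function(e) list(r1 = NA_real_, flagged = NA))
  data.frame(
    n = length(values),
    slope_per_year = ts_fit$slope,
    slope_per_decade = 10 * ts_fit$slope,
    intercept = ts_fit$intercept,
    mk_S = mk$S,
    mk_p = mk$p,
    significant = mk$p < alpha,
    lag1_autocorr = ac$r1,
    lag1_flagged = ac$flagged
  )
}
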
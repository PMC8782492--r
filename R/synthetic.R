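## Synthetic-data generators with known ground truth: a seasonal temperature
## curve, a baseflow-plus-snowmelt-pulse hydrograph, logistic migration
## responses, and noisy annual trend series. Every generator is a pure
## function of (scenario, seed); calling one never disturbs the caller's RNG
## stream.

#' Synthetic study scenario
#'
#' Bundles the parameters of all generators. Defaults mirror the study scale:
#' nine tracked years per herd, two herds, spring-pulse onsets drawn in days
#' 90..125, a snowmelt pulse an order of magnitude above baseflow, and a
#' migration model whose crossing lags the pulse by about 20 days
#' (`beta0 = -5`, `beta_dsm = 0.25`, `beta_herd = -0.25`).
#'
#' @param seed master seed; all per-year generator seeds derive from it.
#' @param years calendar years simulated.
#' @param latitude representative basin latitude (degrees north).
#' @param temp list: `mean` (degC), `amplitude` (degC), `phase_day`,
#'   `noise_sd` (degC). Daily temperature is
#'   `mean + amplitude * sin(2*pi*(i - phase_day)/L) + noise`.
#' @param hydro list: `baseflow`, `magnitude`, `recession` (per day),
#'   `noise_frac` (lognormal sd of multiplicative noise), `onset_days`
#'   (per-year pulse onsets; drawn uniformly in 90..125 when `NULL`).
#' @param migration list: `beta0`, `beta_dsm`, `beta_herd`, `herds`.
#' @return a `gw_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1,
                               years = 2001:2009,
                               latitude = 41,
                               temp = list(mean = 6, amplitude = 12,
                                           phase_day = 105, noise_sd = 2),
                               hydro = list(baseflow = 2, magnitude = 40,
                                            recession = 0.03,
                                            noise_frac = 0.05,
                                            onset_days = NULL),
                               migration = list(beta0 = -5, beta_dsm = 0.25,
                                                beta_herd = -0.25,
                                                herds = c("NAR", "SAR"))) {
  stopifnot(temp$amplitude >= 0, temp$noise_sd >= 0, hydro$baseflow > 0,
            hydro$magnitude >= 0, hydro$recession > 0, hydro$noise_frac >= 0)
  if (is.null(hydro$onset_days)) {
    hydro$onset_days <- with_seed(seed * 7919 + 1, {
      stats::setNames(sample(90:125, length(years), replace = TRUE),
                      as.character(years))
    })
  } else {
    stopifnot(length(hydro$onset_days) == length(years))
    if (any(hydro$onset_days < 30 | hydro$onset_days > 180)) {
      gw_domain_error("pulse onset days must lie in 30..180")
    }
    names(hydro$onset_days) <- as.character(years)
  }
  structure(list(seed = seed, years = years, latitude = latitude,
                 temp = temp, hydro = hydro, migration = migration),
            class = "gw_scenario")
}

year_seed <- function(scenario, year, stream) {
  (scenario$seed * 104729 + year * 389 + stream) %% (.Machine$integer.max - 1L)
}

#' Generate a daily basin temperature series
#'
#' Sinusoidal annual cycle plus iid Gaussian noise:
#' `T_i = mean + amplitude * sin(2*pi*(i - phase_day)/L) + eps_i`. With the
#' default phase day (105) the maximum falls in mid-July and the minimum in
#' mid-January.
#'
#' @param scenario a [synthetic_scenario()].
#' @param year one of `scenario$years`.
#' @return a temperature [daily_series()] covering the year.
#' @export
gen_temperature <- function(scenario, year) {
  L <- year_length(year)
  i <- seq_len(L)
  mu <- scenario$temp$mean +
    scenario$temp$amplitude * sin(2 * pi * (i - scenario$temp$phase_day) / L)
  eps <- with_seed(year_seed(scenario, year, 1L),
                   stats::rnorm(L, 0, scenario$temp$noise_sd))
  daily_series(as.Date(sprintf("%d-01-01", year)) + i - 1, mu + eps,
               id = "synthetic_basin", variable = "temperature")
}

#' Generate a baseflow-plus-spring-pulse hydrograph
#'
#' Flow is `baseflow` before the onset; from the onset it rises linearly to
#' `baseflow + magnitude` over 15 days (`r(k) = (k + 1)/15`, so the onset day
#' itself already carries signal) and then recedes exponentially at the
#' recession rate. Multiplicative lognormal noise with sd `noise_frac` is
#' applied. The true onset day is recorded as attribute `true_onset`.
#'
#' @inheritParams gen_temperature
#' @return a discharge [daily_series()] with attribute `true_onset`.
#' @export
gen_hydrograph <- function(scenario, year) {
  L <- year_length(year)
  onset <- scenario$hydro$onset_days[[as.character(year)]]
  if (is.null(onset)) gw_domain_error(sprintf("year %d not in scenario", year))
  if (onset + 15 > L) gw_domain_error("onset too late to complete the 15-day rise")
  k <- seq_len(L) - onset # days since onset; negative before
  shape <- ifelse(k < 0, 0,
                  ifelse(k < 15, (k + 1) / 15,
                         exp(-scenario$hydro$recession * (k - 14))))
  q <- scenario$hydro$baseflow + scenario$hydro$magnitude * shape
  if (scenario$hydro$noise_frac > 0) {
    q <- q * with_seed(year_seed(scenario, year, 2L),
                       exp(stats::rnorm(L, 0, scenario$hydro$noise_frac)))
  }
  out <- daily_series(as.Date(sprintf("%d-01-01", year)) + seq_len(L) - 1, q,
                      id = "synthetic_gage", variable = "discharge")
  attr(out, "true_onset") <- onset
  out
}

#' True snowmelt covariate table for a scenario
#'
#' Daily `dsm` covariate (`day - true_onset`) for every herd-year over days
#' `1..horizon`, built from the scenario's ground-truth onsets (not from
#' detection). Used to generate responses; end-to-end tests rebuild the
#' covariate from detected pulse days instead.
#'
#' @inheritParams gen_temperature
#' @param horizon last day (default 150).
#' @return data frame: `herd`, `year`, `day`, `dsm`.
#' @export
scenario_covariates <- function(scenario, horizon = 150) {
  grid <- expand.grid(herd = scenario$migration$herds, year = scenario$years,
                      day = seq_len(horizon), stringsAsFactors = FALSE)
  grid$dsm <- grid$day - scenario$hydro$onset_days[as.character(grid$year)]
  grid[order(grid$herd, grid$year, grid$day), ]
}

#' Generate migration responses from a known logistic model
#'
#' Daily probability `theta = logit^{-1}(beta0 + beta_dsm * dsm +
#' beta_herd * [herd == SAR])`. Two modes: `"bernoulli_iid"` draws an
#' independent Bernoulli outcome per day (model-consistent rows, for
#' parameter-recovery studies); `"first_success_step"` sets the ground-truth
#' initiation at the first day a Bernoulli draw succeeds and fills a monotone
#' 0-to-1 step (structure-consistent herd-year responses, for end-to-end
#' tests). Ground-truth initiation days are returned alongside.
#'
#' @param scenario a [synthetic_scenario()].
#' @param covariates data frame `herd`, `year`, `day`, `dsm` (see
#'   [scenario_covariates()]).
#' @param mode `"first_success_step"` (default) or `"bernoulli_iid"`.
#' @param horizon last response day.
#' @return list: `responses` (long data frame `herd`, `year`, `day`,
#'   `response`), `truth` (data frame `herd`, `year`, `initiation_day`; `NA`
#'   when no success occurred by the horizon in step mode).
#' @export
gen_migration_responses <- function(scenario, covariates,
                                    mode = c("first_success_step", "bernoulli_iid"),
                                    horizon = 150) {
  mode <- match.arg(mode)
  b <- scenario$migration
  covariates <- covariates[covariates$day <= horizon, ]
  theta <- stats::plogis(b$beta0 + b$beta_dsm * covariates$dsm +
                           b$beta_herd * as.integer(covariates$herd == "SAR"))
  if (all(theta < 1e-6)) {
    warning("degenerate scenario: migration probability never exceeds 1e-6")
  }
  groups <- split(seq_len(nrow(covariates)),
                  list(covariates$herd, covariates$year), drop = TRUE)
  resp <- integer(nrow(covariates))
  truth <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    idx <- idx[order(covariates$day[idx])]
    hy <- covariates[idx[1], c("herd", "year")]
    u <- with_seed(year_seed(scenario, covariates$year[idx[1]],
                             3L + as.integer(covariates$herd[idx[1]] == "SAR")),
                   stats::runif(length(idx)))
    if (mode == "bernoulli_iid") {
      resp[idx] <- as.integer(u < theta[idx])
      init <- NA_integer_
    } else {
      hit <- which(u < theta[idx])
      init <- if (length(hit)) covariates$day[idx][hit[1]] else NA_integer_
      resp[idx] <- if (is.na(init)) 0L else as.integer(covariates$day[idx] >= init)
    }
    truth[[g]] <- data.frame(herd = hy$herd, year = hy$year, initiation_day = init)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(responses = data.frame(covariates[, c("herd", "year", "day")],
                              response = resp),
       truth = truth[order(truth$herd, truth$year), ])
}

#' Generate an annual series with a known linear trend
#'
#' `y_t = intercept + true_slope * (t - 1) + eps_t` over `n_years` years.
#'
#' @param n_years number of years (`>= 10`).
#' @param true_slope change per year.
#' @param noise_sd iid Gaussian noise sd.
#' @param seed integer seed.
#' @param intercept level in year 1 (default 120).
#' @return numeric vector with attribute `true_slope`.
#' @export
gen_trend_series <- function(n_years, true_slope, noise_sd, seed,
                             intercept = 120) {
  if (n_years < 10) gw_domain_error("n_years must be >= 10")
  y <- intercept + true_slope * (seq_len(n_years) - 1) +
    with_seed(seed, stats::rnorm(n_years, 0, noise_sd))
  attr(y, "true_slope") <- true_slope
  y
}
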
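## End-to-end orchestration: detect pulses, build phenology covariates, fit
## the model suite, predict initiation days, summarize trends and periods.

#' Build the daily covariate table
#'
#' Assembles the per-(year, day) covariates the migration models use:
#' `t_mean` (daily basin temperature), `gdd` (cumulative growing degree day),
#' `jerk` (days since the year's jerk day), and for every flow series
#' `dsm_<name>` (days since the detected spring pulse) and, when requested,
#' `dpsm_<name>` (previous-year-reference variant). Years lacking a complete
#' record for a given source get `NA` in that column.
#'
#' @param temps multi-year temperature [daily_series()], or `NULL` to skip
#'   temperature covariates.
#' @param latitude basin latitude for [base_temperature()].
#' @param flows named list of discharge [daily_series()].
#' @param years years to cover; defaults to the union seen in the inputs.
#' @param horizon last day (default 150).
#' @param max_gap,convention passed to [pulse_features()].
#' @param lagged also compute `dpsm_<name>` columns (default `TRUE`).
#' @return data frame keyed by `year`, `day` with one column per covariate,
#'   with attribute `features` (the per-year feature tables).
#' @export
build_covariate_table <- function(temps = NULL, latitude = 41,
                                  flows = list(), years = NULL, horizon = 150,
                                  max_gap = 7, convention = "min",
                                  lagged = TRUE) {
  if (is.null(years)) {
    years <- sort(unique(c(
      if (!is.null(temps)) series_years(temps),
      unlist(lapply(flows, series_years), use.names = FALSE))))
  }
  tab <- expand.grid(year = years, day = seq_len(horizon))
  tab <- tab[order(tab$year, tab$day), ]
  features <- list()
  if (!is.null(temps)) {
    pheno <- annual_pheno_features(temps, latitude)
    features$pheno <- pheno
    t_base <- base_temperature(latitude)
    tab$t_mean <- NA_real_
    tab$gdd <- NA_real_
    tab$jerk <- NA_real_
    for (yr in years) {
      slice <- year_slice(temps, yr)
      row <- pheno[pheno$year == yr, ]
      if (!nrow(row) || !row$complete) next
      sel <- tab$year == yr
      tab$t_mean[sel] <- slice$value[tab$day[sel]]
      curve <- gdd_series(slice, t_base)
      tab$gdd[sel] <- curve[tab$day[sel]]
      if (row$converged) tab$jerk[sel] <- jerk_covariate(tab$day[sel], row$jerk_day)
    }
  }
  for (nm in names(flows)) {
    feats <- pulse_features(flows[[nm]], max_gap, convention)
    features[[paste0("pulse_", nm)]] <- feats
    col <- paste0("dsm_", nm)
    tab[[col]] <- NA_real_
    for (i in seq_len(nrow(feats))) {
      if (!feats$complete[i]) next
      sel <- tab$year == feats$year[i]
      tab[[col]][sel] <- dsm_covariate(tab$day[sel], feats$pulse_day[i])
    }
    if (lagged) {
      lag <- lagged_pulse_features(flows[[nm]], max_gap, convention)
      features[[paste0("lagged_pulse_", nm)]] <- lag
      lcol <- paste0("dpsm_", nm)
      tab[[lcol]] <- NA_real_
      for (i in seq_len(nrow(lag))) {
        sel <- tab$year == lag$year[i]
        tab[[lcol]][sel] <- dsm_covariate(tab$day[sel], lag$pulse_day[i])
      }
    }
  }
  attr(tab, "features") <- features
  tab
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    gw_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             "gw_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the workflow end to end: generate or read the daily inputs,
#' detect annual spring pulses and phenology features, run trend tests on the
#' annual feature series, fit every requested Bernoulli-logit model
#' specification, score and rank them (highest precision, then highest
#' recall, then lowest DIC), predict per-herd-year initiation days with the
#' top-ranked model, and summarize predictions by historical period. All
#' randomness derives from `config$seed`; the returned bundle carries the
#' seed and a config hash, and re-running an identical config reproduces it
#' exactly.
#'
#' @param config a list (or path to a config file parsed by
#'   [read_pipeline_config()]) with elements:
#'   \describe{
#'     \item{mode}{`"synthetic"` (default) or `"files"`.}
#'     \item{scenario}{a [synthetic_scenario()]; built from `seed` when
#'       absent (synthetic mode).}
#'     \item{flows, temps, migration}{input file paths (files mode); `flows`
#'       is a named vector of daily-values paths.}
#'     \item{latitude, gap_days, convention, horizon}{processing options.}
#'     \item{model_specs}{named list of covariate vectors; empty list gives a
#'       trend-only run.}
#'     \item{mcmc}{list with `chains`, `steps`, `burn_in`.}
#'     \item{period_breaks}{data frame of `start`/`end` years.}
#'     \item{seed}{master seed.}
#'     \item{out_dir}{optional directory; when set, the bundle's tables are
#'       written as CSV plus a JSON-lines run summary.}
#'   }
#' @return a result bundle: `trends`, `features`, `covariates`,
#'   `model_table`, `fits`, `predictions`, `rmse_days`, `periods`, `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  defaults <- list(mode = "synthetic", scenario = NULL, seed = 1,
                   latitude = 41, gap_days = 7, convention = "min",
                   horizon = 150, model_specs = NULL,
                   mcmc = list(chains = 3, steps = 20000, burn_in = 1000),
                   period_breaks = default_period_breaks(),
                   response_mode = "first_success_step")
  config <- utils::modifyList(defaults, config)
  cfg_hash <- rlang::hash(config)
  msg <- function(stage, text) message(sprintf("[%s] %s", stage, text))

  if (config$mode == "synthetic") {
    scen <- config$scenario
    if (is.null(scen)) scen <- synthetic_scenario(seed = config$seed)
    inputs <- run_stage("generate", {
      flows <- list()
      temp_years <- list()
      for (yr in scen$years) {
        temp_years[[as.character(yr)]] <- gen_temperature(scen, yr)
      }
      hydro_years <- lapply(scen$years, function(yr) gen_hydrograph(scen, yr))
      flow <- do.call(rbind, lapply(hydro_years, as.data.frame))
      temps <- do.call(rbind, lapply(temp_years, as.data.frame))
      list(
        temps = daily_series(temps$date, temps$value, "synthetic_basin",
                             "temperature"),
        flows = list(synthetic = daily_series(flow$date, flow$value,
                                              "synthetic_gage", "discharge")),
        truth_onsets = scen$hydro$onset_days)
    })
    msg("generate", sprintf("%d synthetic years, 2 input series", length(scen$years)))
    responses_stage <- run_stage("responses", {
      gen_migration_responses(scen, scenario_covariates(scen, config$horizon),
                              mode = config$response_mode,
                              horizon = config$horizon)
    })
    responses <- responses_stage$responses
    observed <- responses_stage$truth
    names(observed)[names(observed) == "initiation_day"] <- "observed_day"
    if (is.null(config$model_specs)) {
      config$model_specs <- list(dsm = c("dsm_synthetic", "herd"),
                                 gdd = c("gdd", "herd"),
                                 t_mean = c("t_mean", "herd"))
    }
  } else {
    for (p in c(unlist(config$flows), config$temps, config$migration)) {
      if (!is.null(p) && !file.exists(p)) {
        gw_config_error(sprintf("input path does not exist: %s", p))
      }
    }
    inputs <- run_stage("read", {
      flows <- lapply(config$flows, function(p) {
        dialect <- if (grepl("\\.rdb$", p)) "usgs_rdb" else "csv"
        read_daily_values(p, dialect)
      })
      temps <- if (!is.null(config$temps)) {
        read_daily_values(config$temps, "csv", variable = "temperature")
      }
      list(temps = temps, flows = flows)
    })
    records <- run_stage("read", read_migration_table(config$migration))
    responses <- run_stage("responses", build_responses(records, config$horizon))
    observed <- herd_year_stats(records)[, c("herd", "year", "herd_start_day")]
    names(observed)[3] <- "observed_day"
    if (is.null(config$model_specs)) config$model_specs <- list()
  }

  covariates <- run_stage("covariates", {
    build_covariate_table(inputs$temps, config$latitude, inputs$flows,
                          horizon = config$horizon, max_gap = config$gap_days,
                          convention = config$convention)
  })
  features <- attr(covariates, "features")
  msg("covariates", sprintf("%d covariate columns over %d year-days",
                            ncol(covariates) - 2L, nrow(covariates)))

  trends <- run_stage("trends", {
    rows <- list()
    for (nm in names(features)) {
      f <- features[[nm]]
      col <- intersect(c("pulse_day", "gdd180_day", "jerk_day"), names(f))
      for (cc in col) {
        ok <- !is.na(f[[cc]])
        if (sum(ok) < 5) next
        tr <- trend_test(f$year[ok], f[[cc]][ok])
        rows[[paste(nm, cc, sep = ".")]] <- cbind(series = paste(nm, cc, sep = "."), tr)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  msg("trends", sprintf("%d annual series tested", if (is.null(trends)) 0L else nrow(trends)))

  bundle <- list(trends = trends, features = features, covariates = covariates,
                 model_table = NULL, fits = NULL, predictions = NULL,
                 rmse_days = NA_real_, periods = NULL, seed = config$seed,
                 config_hash = cfg_hash)
  if (!length(config$model_specs)) {
    msg("models", "no model specs: trend-only bundle")
    return(write_bundle(bundle, config$out_dir))
  }

  suite <- run_stage("models", {
    model_suite(responses, covariates, specs = config$model_specs,
                chains = config$mcmc$chains, steps = config$mcmc$steps,
                burn_in = config$mcmc$burn_in, seed = config$seed)
  })
  bundle$model_table <- suite$table
  bundle$fits <- suite$fits
  msg("models", sprintf("%d specs fitted; best: %s", nrow(suite$table),
                        suite$table$model[1]))

  best <- suite$fits[[suite$table$model[1]]]
  predictions <- run_stage("predict", {
    rows <- lapply(seq_len(nrow(observed)), function(i) {
      yr <- observed$year[i]
      cov_y <- covariates[covariates$year == yr, , drop = FALSE]
      day <- if (nrow(cov_y) &&
                 !anyNA(cov_y[, setdiff(best$coef_names, c("(Intercept)", "herd"))])) {
        predict_initiation_day(best, cov_y, herd = observed$herd[i],
                               horizon = config$horizon)
      } else NA_integer_
      data.frame(herd = observed$herd[i], year = yr,
                 observed_day = observed$observed_day[i], predicted_day = day)
    })
    do.call(rbind, rows)
  })
  bundle$predictions <- predictions
  ok <- stats::complete.cases(predictions[, c("observed_day", "predicted_day")])
  if (any(ok)) {
    bundle$rmse_days <- prediction_rmse(predictions$predicted_day[ok],
                                        predictions$observed_day[ok])
  }
  msg("predict", sprintf("%d herd-years predicted, RMSE %.2f days",
                         sum(ok), bundle$rmse_days))
  bundle$periods <- run_stage("periods", {
    one <- predictions[predictions$herd == predictions$herd[1], ]
    period_summaries(one$predicted_day, one$year, config$period_breaks)
  })
  write_bundle(bundle, config$out_dir)
}

## write the bundle's tables as CSV plus a JSON-lines run summary
write_bundle <- function(bundle, out_dir) {
  if (is.null(out_dir)) return(bundle)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("trends", "model_table", "predictions", "periods")) {
    if (!is.null(bundle[[nm]])) {
      utils::write.csv(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  lines <- c(
    jsonlite::toJSON(list(record = "run", seed = bundle$seed,
                          config_hash = bundle$config_hash,
                          rmse_days = bundle$rmse_days), auto_unbox = TRUE,
                     digits = NA),
    vapply(names(bundle$fits), function(nm) {
      as.character(jsonlite::toJSON(
        list(record = "fit", model = nm,
             coef = summary(bundle$fits[[nm]])),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"))
    }, character(1)))
  writeLines(lines, file.path(out_dir, "summary.jsonl"))
  bundle
}

#' Parse a flat key = value pipeline config file
#'
#' Sections in square brackets prefix the keys that follow
#' (`[mcmc]` + `steps = 5000` becomes `config$mcmc$steps`). Values are split
#' on commas and coerced to numeric where possible. The `[flows]` section
#' maps station names to file paths. Lines starting with `#` are comments.
#'
#' @param path config file path.
#' @return nested list usable as [run_pipeline()] config.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) gw_config_error(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  config <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) gw_config_error(sprintf("malformed config line: %s", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!anyNA(num)) num else parts
    if (is.null(section)) {
      config[[key]] <- val
    } else {
      config[[section]][[key]] <- val
    }
  }
  config
}
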
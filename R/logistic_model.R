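## Bayesian Bernoulli-logit migration model: design assembly, multicollinearity
## screen, random-walk Metropolis fit with diffuse normal priors, DIC and
## posterior-predictive recall/precision scoring, daily initiation prediction.

#' Assemble a daily design matrix
#'
#' Joins the long-format daily responses with per-(year, day) covariates and
#' appends a herd dummy (NAR = 0, SAR = 1) when the model specification names
#' `"herd"`. One row per herd-year-day; an implicit intercept column of ones
#' is always included.
#'
#' @param responses data frame `herd`, `year`, `day`, `response` (see
#'   [build_responses()] or [gen_migration_responses()]).
#' @param covariates data frame keyed by `year` and `day` with one column per
#'   covariate (e.g. `dsm_slater`, `gdd`, `jerk`, `t_mean`). If covariates
#'   differ by herd, include a `herd` column and the join also uses it.
#' @param model_spec character vector of covariate names; `"herd"` requests
#'   the herd dummy.
#' @return a `gw_design` list: `X` (with intercept), `y`, `meta`
#'   (herd/year/day), `terms`.
#' @export
assemble_design <- function(responses, covariates, model_spec) {
  terms <- setdiff(model_spec, "herd")
  missing_cov <- setdiff(terms, names(covariates))
  if (length(missing_cov)) {
    gw_assembly_error(sprintf("covariates absent from table: %s",
                              paste(missing_cov, collapse = ", ")))
  }
  keys <- intersect(c("herd", "year", "day"), names(covariates))
  merged <- merge(responses, covariates[, c(keys, terms), drop = FALSE],
                  by = keys, all.x = TRUE, sort = FALSE)
  if (length(terms)) {
    bad <- !stats::complete.cases(merged[, terms, drop = FALSE])
    if (any(bad)) {
      gaps <- unique(merged$year[bad])
      gw_assembly_error(sprintf("missing covariate values for year(s): %s",
                                paste(sort(gaps), collapse = ", ")))
    }
  }
  merged <- merged[order(merged$herd, merged$year, merged$day), ]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(merged[, terms, drop = FALSE]))
  if ("herd" %in% model_spec) {
    X <- cbind(X, herd = as.integer(merged$herd == "SAR"))
  }
  structure(list(X = X, y = as.integer(merged$response),
                 meta = merged[, c("herd", "year", "day")],
                 terms = model_spec),
            class = "gw_design")
}

#' Pairwise multicollinearity screen
#'
#' All pairwise Pearson correlations between (non-intercept) covariate
#' columns; pairs with `|R|` above the threshold are flagged as having high
#' potential for multicollinearity effects when used in the same model.
#'
#' @param design a `gw_design` or a plain numeric matrix of covariates.
#' @param threshold flag level on `|R|`; default 0.20.
#' @return data frame: `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_screen <- function(design, threshold = 0.20) {
  M <- if (inherits(design, "gw_design")) {
    design$X[, colnames(design$X) != "(Intercept)", drop = FALSE]
  } else {
    as.matrix(design)
  }
  if (ncol(M) < 2) gw_insufficient_data("need at least 2 covariates")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    gw_domain_error(sprintf("undefined correlation: zero-variance column(s) %s",
                            paste(colnames(M)[sds == 0], collapse = ", ")))
  }
  R <- stats::cor(M)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  data.frame(var1 = colnames(M)[idx[, 1]], var2 = colnames(M)[idx[, 2]],
             r = R[idx], flagged = abs(R[idx]) > threshold)
}

log_posterior_factory <- function(X, y, prior_sd) {
  pos <- y == 1L
  function(beta) {
    eta <- drop(X %*% beta)
    sum(stats::plogis(eta[pos], log.p = TRUE)) +
      sum(stats::plogis(-eta[!pos], log.p = TRUE)) +
      sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))
  }
}

#' Fit the Bernoulli-logit model by MCMC
#'
#' Model: `y_i ~ Bernoulli(theta_i)`, `logit(theta_i) = x_i' beta`, with
#' independent diffuse priors `beta_k ~ N(0, sd = prior_sd)` (default sd 100,
#' i.e. precision 1e-4). The sampler is a joint random-walk Metropolis whose
#' Gaussian proposal uses the maximum-likelihood Fisher covariance scaled by
#' `2.38^2 / K`; chains start at the MLE jittered by one proposal draw.
#' Convergence is reported per coefficient via the Gelman-Rubin statistic
#' ([coda::gelman.diag()]); the fit is flagged unconverged when any
#' R-hat exceeds 1.1. Covariates enter unstandardized.
#'
#' @param design a `gw_design` from [assemble_design()].
#' @param chains number of chains (default 3).
#' @param steps retained steps per chain (default 20000).
#' @param burn_in discarded initial steps per chain (default 1000).
#' @param seed integer seed; chain seeds are derived from it.
#' @param prior_sd prior standard deviation for every coefficient.
#' @param model_id optional label carried into summaries.
#' @return a `gw_fit`: `draws` (list of steps x K matrices), `coef_names`,
#'   `rhat`, `converged`, `accept_rate`, sampler settings, `model_spec`,
#'   `model_id`.
#' @export
fit_bayes_logistic <- function(design, chains = 3, steps = 20000,
                               burn_in = 1000, seed = 1, prior_sd = 100,
                               model_id = NULL) {
  X <- design$X
  y <- design$y
  if (!length(y)) gw_domain_error("empty design")
  if (length(unique(y)) < 2) {
    gw_fit_error("response has a single class: complete separation, no fit")
  }
  nonint <- colnames(X) != "(Intercept)"
  if (any(apply(X[, nonint, drop = FALSE], 2, stats::sd) == 0)) {
    gw_fit_error("zero-variance covariate column")
  }
  K <- ncol(X)
  mle <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta_hat <- mle$coefficients
  p_hat <- stats::plogis(drop(X %*% beta_hat))
  V <- tryCatch(chol2inv(chol(crossprod(X, X * (p_hat * (1 - p_hat))))),
                error = function(e) diag(K))
  L <- t(chol(V * 2.38^2 / K)) # proposal factor
  logpost <- log_posterior_factory(X, y, prior_sd)
  draws <- vector("list", chains)
  accept <- numeric(chains)
  with_seed(seed, {
    chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  })
  for (c in seq_len(chains)) {
    with_seed(chain_seeds[c], {
      b <- beta_hat + drop(L %*% stats::rnorm(K))
      lp <- logpost(b)
      out <- matrix(NA_real_, steps, K, dimnames = list(NULL, colnames(X)))
      acc <- 0L
      for (it in seq_len(burn_in + steps)) {
        bp <- b + drop(L %*% stats::rnorm(K))
        lpp <- logpost(bp)
        if (log(stats::runif(1)) < lpp - lp) {
          b <- bp; lp <- lpp; acc <- acc + 1L
        }
        if (it > burn_in) out[it - burn_in, ] <- b
      }
      draws[[c]] <- out
      accept[c] <- acc / (burn_in + steps)
    })
  }
  rhat <- rep(NA_real_, K)
  if (chains >= 2) {
    ml <- coda::as.mcmc.list(lapply(draws, coda::mcmc))
    rhat <- coda::gelman.diag(ml, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  }
  structure(list(draws = draws, coef_names = colnames(X), rhat = rhat,
                 converged = all(is.na(rhat)) || all(rhat < 1.1, na.rm = TRUE),
                 accept_rate = accept, chains = chains, steps = steps,
                 burn_in = burn_in, prior_sd = prior_sd, seed = seed,
                 model_spec = design$terms, model_id = model_id),
            class = "gw_fit")
}

pooled_draws <- function(fit, max_draws = Inf) {
  A <- do.call(rbind, fit$draws)
  if (nrow(A) > max_draws) {
    A <- A[round(seq(1, nrow(A), length.out = max_draws)), , drop = FALSE]
  }
  A
}

#' @export
print.gw_fit <- function(x, ...) {
  cat(sprintf("<gw_fit> %s: %d chains x %d steps (burn-in %d), accept %.2f\n",
              if (is.null(x$model_id)) paste(x$model_spec, collapse = "+") else x$model_id,
              x$chains, x$steps, x$burn_in, mean(x$accept_rate)))
  print(summary(x))
  invisible(x)
}

#' Posterior coefficient summary
#'
#' @param object a `gw_fit`.
#' @param ... unused.
#' @return data frame: posterior `mean`, `sd`, `q2.5`, `q50`, `q97.5`,
#'   `rhat`, and `excludes_zero` (the 95% credible interval does not contain
#'   zero) per coefficient.
#' @export
summary.gw_fit <- function(object, ...) {
  A <- pooled_draws(object)
  q <- t(apply(A, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  data.frame(coef = object$coef_names, mean = colMeans(A), sd = apply(A, 2, stats::sd),
             q2.5 = q[, 1], q50 = q[, 2], q97.5 = q[, 3], rhat = object$rhat,
             excludes_zero = q[, 1] > 0 | q[, 3] < 0, row.names = NULL)
}

deviance_at <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  -2 * (sum(stats::plogis(eta[y == 1L], log.p = TRUE)) +
          sum(stats::plogis(-eta[y == 0L], log.p = TRUE)))
}

#' Model scores: DIC and posterior-predictive recall/precision
#'
#' DIC is `Dbar + pD` where `Dbar` is the posterior mean deviance,
#' `pD = Dbar - D(beta_bar)` the effective number of parameters, and deviance
#' is `-2 log L`. Classification calls a row positive when its posterior
#' median probability exceeds the threshold (0.5); because the logit link is
#' monotone, the median probability crosses 0.5 exactly when the median
#' linear predictor crosses 0. Recall is `TP / (TP + FN)`; precision is
#' `TP / (TP + FP)` (`NA` with a warning when nothing is predicted positive).
#' Deviance and medians are computed over at most `max_draws` evenly thinned
#' pooled draws.
#'
#' @param fit a `gw_fit`.
#' @param design the `gw_design` the fit used (or any compatible one).
#' @param threshold classification threshold on the posterior-median
#'   probability.
#' @param max_draws thinning cap for scoring.
#' @return list: `dic`, `p_d`, `dbar`, `recall`, `precision`, `confusion`.
#' @export
model_scores <- function(fit, design, threshold = 0.5, max_draws = 3000) {
  X <- design$X[, fit$coef_names, drop = FALSE]
  y <- design$y
  A <- pooled_draws(fit, max_draws)
  dbar <- mean(apply(A, 1, function(b) deviance_at(b, X, y)))
  dhat <- deviance_at(colMeans(A), X, y)
  eta_draws <- X %*% t(A) # rows x draws
  eta_med <- apply(eta_draws, 1, stats::median)
  pred <- eta_med > stats::qlogis(threshold)
  tp <- sum(pred & y == 1L)
  fn <- sum(!pred & y == 1L)
  fp <- sum(pred & y == 0L)
  tn <- sum(!pred & y == 0L)
  precision <- if (tp + fp == 0) {
    warning("no predicted positives: precision undefined")
    NA_real_
  } else tp / (tp + fp)
  list(dic = 2 * dbar - dhat, p_d = dbar - dhat, dbar = dbar,
       recall = tp / (tp + fn), precision = precision,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Predicted migration-initiation day for one herd-year
#'
#' The first day on which the posterior median of
#' `theta_i = logit^{-1}(x_i' beta)` exceeds 0.5 (equivalently, the median
#' linear predictor exceeds 0), over days `1..horizon`.
#'
#' @param fit a `gw_fit`.
#' @param covariates data frame for one herd-year with `day` and the fit's
#'   covariate columns.
#' @param herd `"NAR"` or `"SAR"`; used when the fit includes the herd dummy.
#' @param horizon last day scanned (default 150).
#' @param max_draws thinning cap.
#' @return Julian day (integer), or `NA` when the probability never exceeds
#'   0.5.
#' @export
predict_initiation_day <- function(fit, covariates, herd = "NAR",
                                   horizon = 150, max_draws = 3000) {
  covariates <- covariates[order(covariates$day), , drop = FALSE]
  covariates <- covariates[covariates$day <= horizon, , drop = FALSE]
  if (!nrow(covariates) || !setequal(covariates$day, seq_len(horizon))) {
    gw_assembly_error(sprintf("covariates must cover days 1..%d", horizon))
  }
  terms <- setdiff(fit$coef_names, c("(Intercept)", "herd"))
  missing_cov <- setdiff(terms, names(covariates))
  if (length(missing_cov)) {
    gw_assembly_error(sprintf("covariates absent: %s",
                              paste(missing_cov, collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates[, terms, drop = FALSE]))
  if ("herd" %in% fit$coef_names) {
    X <- cbind(X, herd = as.integer(herd == "SAR"))
  }
  X <- X[, fit$coef_names, drop = FALSE]
  A <- pooled_draws(fit, max_draws)
  eta_med <- apply(X %*% t(A), 1, stats::median)
  day <- which(eta_med > 0)[1]
  if (is.na(day)) NA_integer_ else as.integer(covariates$day[day])
}

#' Root-mean-square error between predicted and observed initiation days
#'
#' @param predicted,observed numeric vectors paired by position (or by names
#'   when both are named).
#' @return RMSE in days.
#' @export
prediction_rmse <- function(predicted, observed) {
  if (!is.null(names(predicted)) && !is.null(names(observed))) {
    if (!setequal(names(predicted), names(observed))) {
      gw_domain_error("predicted and observed names do not pair up")
    }
    observed <- observed[names(predicted)]
  }
  if (!length(predicted) || length(predicted) != length(observed)) {
    gw_domain_error("predicted and observed must pair up and be nonempty")
  }
  if (anyNA(predicted) || anyNA(observed)) {
    gw_domain_error("NA in paired predictions/observations")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Default historical periods
#'
#' Period breaks used to summarize predicted initiation days over the
#' streamgage period of record: 1943-1959, 1960-1979, 1980-1999, 2000-2018.
#'
#' @return data frame with `start` and `end` year per period.
#' @export
default_period_breaks <- function() {
  data.frame(start = c(1943L, 1960L, 1980L, 2000L),
             end = c(1959L, 1979L, 1999L, 2018L))
}

#' Median and interquartile range of predicted days per period
#'
#' @param days predicted initiation days.
#' @param years matching years (each must fall in exactly one period).
#' @param breaks data frame of `start`/`end` years; default
#'   [default_period_breaks()].
#' @return data frame: `period`, `start`, `end`, `n`, `median_day`, `iqr_days`
#'   (`NA` with a message for an empty period).
#' @export
period_summaries <- function(days, years, breaks = default_period_breaks()) {
  stopifnot(length(days) == length(years))
  rows <- lapply(seq_len(nrow(breaks)), function(i) {
    inside <- years >= breaks$start[i] & years <= breaks$end[i]
    d <- days[inside & !is.na(days)]
    if (!length(d)) {
      message(sprintf("period %d-%d: no predictions", breaks$start[i], breaks$end[i]))
      return(data.frame(period = sprintf("%d-%d", breaks$start[i], breaks$end[i]),
                        start = breaks$start[i], end = breaks$end[i], n = 0L,
                        median_day = NA_real_, iqr_days = NA_real_))
    }
    data.frame(period = sprintf("%d-%d", breaks$start[i], breaks$end[i]),
               start = breaks$start[i], end = breaks$end[i], n = length(d),
               median_day = stats::median(d), iqr_days = stats::IQR(d))
  })
  do.call(rbind, rows)
}

#' The ten-model comparison suite
#'
#' Fits a list of model specifications on shared responses/covariates and
#' tabulates coefficients (with 95% credible intervals), DIC, recall, and
#' precision, ordered by priority of highest precision, then highest recall,
#' then lowest DIC. The default specifications are the ten single- and
#' multi-covariate Bernoulli-logit variants combining basin temperature, GDD,
#' jerk, and the snowmelt covariates with the herd dummy.
#'
#' @param responses,covariates as in [assemble_design()].
#' @param specs named list of model specifications (character vectors).
#' @param ... passed to [fit_bayes_logistic()] (chains, steps, seed, ...).
#' @return list: `table` (one row per model) and `fits` (named list of
#'   `gw_fit`).
#' @export
model_suite <- function(responses, covariates, specs = default_model_specs(),
                        ...) {
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    design <- assemble_design(responses, covariates, specs[[nm]])
    fit <- fit_bayes_logistic(design, model_id = nm, ...)
    sc <- model_scores(fit, design)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm,
                             spec = paste(specs[[nm]], collapse = "+"),
                             dic = sc$dic, recall = sc$recall,
                             precision = sc$precision,
                             converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$precision, -tab$recall, tab$dic), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' @rdname model_suite
#' @export
default_model_specs <- function() {
  list(m1 = c("t_mean", "herd"),
       m2 = c("gdd", "herd"),
       m3 = c("jerk", "herd"),
       m4 = c("dsm_lily", "herd"),
       m5 = c("dsm_slater", "herd"),
       m6 = c("dpsm_slater", "herd"),
       m7 = c("t_mean", "dsm_slater", "herd"),
       m8 = c("t_mean", "dpsm_slater", "herd"),
       m9 = c("t_mean", "gdd", "dsm_slater", "herd"),
       m10 = c("t_mean", "gdd", "dpsm_slater", "herd"))
}
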
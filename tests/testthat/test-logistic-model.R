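make_responses <- function(init_by_hy, horizon = 150) {
  do.call(rbind, lapply(seq_len(nrow(init_by_hy)), function(i) {
    data.frame(herd = init_by_hy$herd[i], year = init_by_hy$year[i],
               day = seq_len(horizon),
               response = as.integer(seq_len(horizon) >= init_by_hy$init[i]))
  }))
}

test_that("design assembly joins covariates and appends the herd dummy", {
  resp <- make_responses(data.frame(herd = c("NAR", "SAR"), year = 2005,
                                    init = c(120, 110)))
  cov <- data.frame(year = 2005, day = 1:150, dsm = (1:150) - 100)
  d <- assemble_design(resp, cov, c("dsm", "herd"))
  expect_equal(nrow(d$X), 300)
  expect_equal(colnames(d$X), c("(Intercept)", "dsm", "herd"))
  expect_equal(sort(unique(d$X[, "herd"])), c(0, 1))
  expect_equal(d$y[d$meta$herd == "NAR"][120], 1L)
  expect_error(assemble_design(resp, cov, c("gdd", "herd")),
               class = "gw_assembly_error")
  cov_gap <- cov
  cov_gap$dsm[5] <- NA
  expect_error(assemble_design(resp, cov_gap, c("dsm", "herd")),
               "2005", class = "gw_assembly_error")
})

test_that("collinearity screen flags |R| above 0.20", {
  set.seed(701)
  x <- rnorm(1e4)
  dup <- cbind(a = x, b = x)
  scr <- collinearity_screen(dup)
  expect_equal(scr$r, 1)
  expect_true(scr$flagged)

  neg <- collinearity_screen(cbind(a = x, b = -x))
  expect_equal(neg$r, -1)
  expect_true(neg$flagged) # absolute-value rule

  indep <- collinearity_screen(cbind(a = x, b = rnorm(1e4)))
  expect_lt(abs(indep$r), 0.20)
  expect_false(indep$flagged)

  expect_error(collinearity_screen(cbind(a = x, b = rep(1, 1e4))),
               class = "gw_domain_error")
})

test_that("degenerate designs are rejected before sampling", {
  X <- cbind(`(Intercept)` = 1, x = rnorm(50))
  ones <- structure(list(X = X, y = rep(1L, 50), terms = "x"), class = "gw_design")
  expect_error(fit_bayes_logistic(ones), class = "gw_fit_error")
  flat <- structure(list(X = cbind(`(Intercept)` = 1, x = rep(2, 50)),
                         y = rep(c(0L, 1L), 25), terms = "x"),
                    class = "gw_design")
  expect_error(fit_bayes_logistic(flat), class = "gw_fit_error")
})

test_that("intercept-only fit on a balanced response centers near zero", {
  d <- structure(list(X = cbind(`(Intercept)` = rep(1, 400)),
                      y = rep(c(0L, 1L), 200), terms = character()),
                 class = "gw_design")
  fit <- fit_bayes_logistic(d, chains = 2, steps = 2000, burn_in = 500, seed = 9)
  expect_lt(abs(summary(fit)$mean), 0.2)
  expect_true(fit$converged)
})

test_that("posterior means agree with the glm MLE under diffuse priors", {
  set.seed(702)
  n <- 800
  x <- runif(n, -60, 40)
  y <- rbinom(n, 1, plogis(-4 + 0.2 * x))
  d <- structure(list(X = cbind(`(Intercept)` = 1, dsm = x), y = y,
                      terms = "dsm"), class = "gw_design")
  fit <- fit_bayes_logistic(d, chains = 3, steps = 4000, burn_in = 1000, seed = 3)
  s <- summary(fit)
  ml <- glm(y ~ x, family = binomial())
  se <- sqrt(diag(vcov(ml)))
  expect_lt(abs(s$mean[1] - coef(ml)[1]), se[1])
  expect_lt(abs(s$mean[2] - coef(ml)[2]), se[2])
  expect_true(all(fit$rhat < 1.1))
})

test_that("posterior matches an independent Gibbs sampler on the same data", {
  set.seed(703)
  n <- 400
  x <- runif(n, -50, 50)
  y <- rbinom(n, 1, plogis(-2 + 0.15 * x))
  d <- structure(list(X = cbind(`(Intercept)` = 1, dsm = x), y = y,
                      terms = "dsm"), class = "gw_design")
  fit <- fit_bayes_logistic(d, chains = 2, steps = 4000, burn_in = 1000, seed = 5)
  s <- summary(fit)

  library(rjags)
  model_str <- "model {
    for (i in 1:N) { y[i] ~ dbern(ilogit(b0 + b1 * x[i])) }
    b0 ~ dnorm(0, 1.0E-4)
    b1 ~ dnorm(0, 1.0E-4)
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(x = x, y = y, N = n), n.chains = 2,
                   inits = lapply(1:2, function(c)
                     list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 50 + c)),
                   quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  sj <- summary(coda.samples(jm, c("b0", "b1"), 4000, progress.bar = "none"))
  expect_lt(abs(s$mean[1] - sj$statistics["b0", "Mean"]),
            0.3 * sj$statistics["b0", "SD"])
  expect_lt(abs(s$mean[2] - sj$statistics["b1", "Mean"]),
            0.3 * sj$statistics["b1", "SD"])
})

test_that("DIC equals the hand-computed deviance decomposition", {
  X <- cbind(`(Intercept)` = 1, x = c(-2, -1, 1, 2))
  y <- c(0L, 0L, 1L, 1L)
  draws <- cbind(`(Intercept)` = c(0.1, -0.1), x = c(1.2, 0.8))
  fit <- fixed_fit(draws)
  d <- structure(list(X = X, y = y, terms = "x"), class = "gw_design")
  sc <- model_scores(fit, d)
  dev <- function(b) -2 * sum(dbinom(y, 1, plogis(drop(X %*% b)), log = TRUE))
  dbar <- mean(apply(draws, 1, dev))
  dhat <- dev(colMeans(draws))
  expect_equal(sc$dbar, dbar)
  expect_equal(sc$p_d, dbar - dhat)
  expect_equal(sc$dic, dbar + (dbar - dhat))
})

test_that("recall and precision follow the confusion-matrix formulas", {
  X <- cbind(`(Intercept)` = 1, x = c(-3, -2, -1, 1, 2, 3))
  y <- as.integer(X[, "x"] > 0)
  fit <- fixed_fit(cbind(`(Intercept)` = c(0, 0), x = c(5, 5)))
  d <- structure(list(X = X, y = y, terms = "x"), class = "gw_design")
  sc <- model_scores(fit, d)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)

  # one false negative, one false positive
  y2 <- c(0L, 0L, 1L, 0L, 1L, 1L)
  d2 <- structure(list(X = X, y = y2, terms = "x"), class = "gw_design")
  sc2 <- model_scores(fit, d2)
  expect_equal(unname(sc2$confusion["tp"]), 2)
  expect_equal(sc2$recall, 2 / (2 + 1))
  expect_equal(sc2$precision, 2 / (2 + 1))

  fit_neg <- fixed_fit(cbind(`(Intercept)` = c(-10, -10), x = c(0, 0)))
  expect_warning(sc3 <- model_scores(fit_neg, d), "no predicted positives")
  expect_true(is.na(sc3$precision))
})

test_that("predicted initiation is the first day median probability exceeds 0.5", {
  pulse <- 100
  cov <- data.frame(day = 1:150, dsm = (1:150) - pulse)
  fit <- fixed_fit(cbind(`(Intercept)` = c(0, 0, 0), dsm = c(0.3, 0.25, 0.2)))
  # with beta0 = 0 and beta1 > 0, theta crosses 0.5 at the first dsm > 0 day
  expect_equal(predict_initiation_day(fit, cov), pulse + 1L)

  # linear predictor negative on every day of the horizon
  fit_neg <- fixed_fit(cbind(`(Intercept)` = c(-5, -5), dsm = c(0.01, 0.01)))
  expect_true(is.na(predict_initiation_day(fit_neg, cov)))

  fit_int <- fixed_fit(cbind(`(Intercept)` = c(2, 2), dsm = c(0, 0)))
  expect_equal(predict_initiation_day(fit_int, cov), 1L)

  expect_error(predict_initiation_day(fit, cov[1:10, ]),
               class = "gw_assembly_error")
})

test_that("raising a positive-coefficient covariate never delays the prediction", {
  fit <- fixed_fit(cbind(`(Intercept)` = rep(-1, 3), dsm = c(0.2, 0.25, 0.3)))
  prev <- Inf
  for (shift in c(0, 2, 5, 10)) {
    cov <- data.frame(day = 1:150, dsm = (1:150) - 110 + shift)
    day <- predict_initiation_day(fit, cov)
    expect_lte(day, prev)
    prev <- day
  }
})

test_that("RMSE and period summaries follow their definitions", {
  expect_equal(prediction_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(prediction_rmse(c(10, 10), c(7, 6)), sqrt(12.5))
  expect_equal(prediction_rmse(100, 105), 5)
  expect_error(prediction_rmse(1:3, 1:2), class = "gw_domain_error")
  expect_error(prediction_rmse(c(a = 1), c(b = 1)), class = "gw_domain_error")

  ps <- period_summaries(c(110, 120, 130), c(1945, 1950, 1955),
                         breaks = data.frame(start = 1943, end = 1959))
  expect_equal(ps$median_day, 120)
  expect_equal(ps$iqr_days, 10)
  one <- period_summaries(118, 2005, data.frame(start = 2000, end = 2018))
  expect_equal(one$median_day, 118)
  expect_equal(one$iqr_days, 0)
  expect_message(
    empty <- period_summaries(118, 2005, data.frame(start = 1943, end = 1959)),
    "no predictions")
  expect_true(is.na(empty$median_day))
})
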
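test_that("generators are pure functions of the scenario seed", {
  scen <- synthetic_scenario(seed = 42)
  expect_equal(gen_temperature(scen, 2003)$value,
               gen_temperature(scen, 2003)$value)
  expect_equal(gen_hydrograph(scen, 2003)$value,
               gen_hydrograph(scen, 2003)$value)
  r1 <- gen_migration_responses(scen, scenario_covariates(scen))
  r2 <- gen_migration_responses(scen, scenario_covariates(scen))
  expect_identical(r1, r2)
  # and a generator call does not disturb the caller's RNG stream
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(gen_temperature(scen, 2004))
  expect_identical(runif(1), a)
})

test_that("temperature generator honors its parameters", {
  scen0 <- synthetic_scenario(seed = 1, temp = list(mean = 6, amplitude = 12,
                                                    phase_day = 105, noise_sd = 0))
  ts <- gen_temperature(scen0, 2003)
  i <- 1:365
  expect_equal(ts$value, 6 + 12 * sin(2 * pi * (i - 105) / 365))
  expect_equal(which.max(ts$value), 105 + round(365 / 4)) # peak a quarter-cycle after phase day

  flat <- synthetic_scenario(seed = 1, temp = list(mean = 6, amplitude = 0,
                                                   phase_day = 105, noise_sd = 0))
  expect_equal(unique(gen_temperature(flat, 2003)$value), 6)
})

test_that("hydrograph generator encodes a detectable onset", {
  scen <- synthetic_scenario(seed = 2, years = 2002:2004,
                             hydro = list(baseflow = 2, magnitude = 40,
                                          recession = 0.03, noise_frac = 0,
                                          onset_days = c(100, 90, 110)))
  hg <- gen_hydrograph(scen, 2002)
  expect_equal(attr(hg, "true_onset"), 100)
  expect_equal(hg$value[99], 2) # baseflow up to the day before onset
  expect_gt(hg$value[100], 2) # signal on the onset day itself
  det <- spring_pulse_day(hg$value, mean(hg$value))
  expect_true(det >= 98 && det <= 100)

  # flat hydrograph (zero magnitude): detector falls back to the tie rule
  flat <- synthetic_scenario(seed = 2, years = 2002,
                             hydro = list(baseflow = 2, magnitude = 0,
                                          recession = 0.03, noise_frac = 0,
                                          onset_days = 100))
  fh <- gen_hydrograph(flat, 2002)
  expect_equal(spring_pulse_day(fh$value, mean(fh$value)), 1L)

  late <- synthetic_scenario(seed = 2, years = 2002,
                             hydro = list(baseflow = 2, magnitude = 40,
                                          recession = 0.03, noise_frac = 0,
                                          onset_days = 170))
  late$hydro$onset_days[["2002"]] <- 360 # rise cannot complete within the year
  expect_error(gen_hydrograph(late, 2002), class = "gw_domain_error")
  expect_error(synthetic_scenario(seed = 2, years = 2002,
                                  hydro = list(baseflow = 2, magnitude = 40,
                                               recession = 0.03, noise_frac = 0,
                                               onset_days = 200)),
               class = "gw_domain_error")

  # onsets trending earlier give a negative Theil-Sen slope on detected days
  feats <- do.call(rbind, lapply(scen$years, function(y) {
    h <- gen_hydrograph(scen, y)
    data.frame(year = y, day = spring_pulse_day(h$value, mean(h$value)))
  }))
  scen_dec <- synthetic_scenario(seed = 2, years = 2002:2004,
                                 hydro = list(baseflow = 2, magnitude = 40,
                                              recession = 0.03, noise_frac = 0,
                                              onset_days = c(110, 100, 90)))
  feats_dec <- do.call(rbind, lapply(scen_dec$years, function(y) {
    h <- gen_hydrograph(scen_dec, y)
    data.frame(year = y, day = spring_pulse_day(h$value, mean(h$value)))
  }))
  expect_lt(theil_sen(feats_dec$year, feats_dec$day)$slope, 0)
})

test_that("migration responses follow the generating logistic model", {
  # near-deterministic limit: initiation lands on the first dsm > 0 day
  scen <- synthetic_scenario(seed = 3, years = 2002:2003,
                             hydro = list(baseflow = 2, magnitude = 40,
                                          recession = 0.03, noise_frac = 0,
                                          onset_days = c(100, 95)),
                             migration = list(beta0 = -30, beta_dsm = 1000,
                                              beta_herd = 0,
                                              herds = c("NAR", "SAR")))
  rr <- gen_migration_responses(scen, scenario_covariates(scen))
  # truth is ordered by herd then year; onsets 100/95 put initiation at 101/96
  expect_equal(rr$truth$initiation_day, c(101L, 96L, 101L, 96L))

  # certain-migration limit: initiation on day 1
  scen1 <- synthetic_scenario(seed = 3, years = 2002,
                              hydro = list(baseflow = 2, magnitude = 40,
                                           recession = 0.03, noise_frac = 0,
                                           onset_days = 100),
                              migration = list(beta0 = 30, beta_dsm = 0,
                                               beta_herd = 0,
                                               herds = c("NAR", "SAR")))
  rr1 <- gen_migration_responses(scen1, scenario_covariates(scen1))
  expect_equal(rr1$truth$initiation_day, c(1L, 1L))

  # each herd-year response is a monotone step starting at its truth day
  scen2 <- synthetic_scenario(seed = 4)
  rr2 <- gen_migration_responses(scen2, scenario_covariates(scen2))
  for (i in seq_len(nrow(rr2$truth))) {
    r <- rr2$responses$response[rr2$responses$herd == rr2$truth$herd[i] &
                                  rr2$responses$year == rr2$truth$year[i]]
    expect_equal(r, as.integer(seq_len(150) >= rr2$truth$initiation_day[i]))
  }

  degen <- synthetic_scenario(seed = 3, years = 2002,
                              hydro = list(baseflow = 2, magnitude = 40,
                                           recession = 0.03, noise_frac = 0,
                                           onset_days = 100),
                              migration = list(beta0 = -80, beta_dsm = 0,
                                               beta_herd = 0,
                                               herds = c("NAR", "SAR")))
  expect_warning(gen_migration_responses(degen, scenario_covariates(degen)),
                 "degenerate")
})

test_that("trend generator records its truth and recovers it noiselessly", {
  y <- gen_trend_series(76, true_slope = -0.17, noise_sd = 0, seed = 10)
  expect_equal(attr(y, "true_slope"), -0.17)
  expect_equal(theil_sen(seq_len(76), as.numeric(y))$slope * 10, -1.7)
  expect_error(gen_trend_series(5, 0, 1, 1), class = "gw_domain_error")
})
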
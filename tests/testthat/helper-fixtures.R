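# Shared fixture builders: everything is generated in code at test time.

# A small NWIS-style daily-values RDB export, written by hand.
write_rdb_fixture <- function(path) {
  writeLines(c(
    "# ---------------------------------- WARNING ----------------------------------------",
    "# Provisional data are subject to revision.",
    "#",
    "agency_cd\tsite_no\tdatetime\t01234_00060_00003\t01234_00060_00003_cd",
    "5s\t15s\t20d\t14n\t10s",
    "USGS\t09253000\t2015-03-01\t11.5\tA",
    "USGS\t09253000\t2015-03-02\t12.0 A\t",
    "USGS\t09253000\t2015-03-03\tIce\t",
    "USGS\t09253000\t2015-03-04\t13.25\tA e",
    "USGS\t09253000\t2015-03-05\t14\tP"
  ), path)
  path
}

# Per-animal migration intervals engineered to match one herd-year summary
# row: n animals, earliest individual start, group start day reached first at
# herd_start_day by max_simultaneous animals, all displacements equal to the
# row's median.
intervals_from_summary <- function(row) {
  m <- row$max_simultaneous
  s <- row$herd_start_day
  e <- min(s + 20L, 366L)
  starts <- s0 <- row$indiv_start_day
  ends <- e
  if (m > 1) {
    starts <- c(starts, rep(s, m - 1L))
    ends <- c(ends, rep(e, m - 1L))
  }
  extras <- row$n - m
  if (extras > 0) {
    # disjoint one-day intervals strictly between the earliest individual and
    # the group start keep interim counts at 2 < m
    days <- seq(s0 + 1L, s - 1L)[seq_len(extras)]
    starts <- c(starts, days)
    ends <- c(ends, days)
  }
  migration_records(
    animal_id = sprintf("%s%d_%02d", row$herd, row$year, seq_along(starts)),
    herd = rep(row$herd, length(starts)),
    year = rep(row$year, length(starts)),
    start_day = starts, end_day = ends,
    displacement_km = rep(row$median_displacement_km, length(starts))
  )
}

# One complete calendar year of constant temperature as a daily_series.
constant_year_temps <- function(year, value) {
  n <- julian_day(as.Date(sprintf("%d-12-31", year)))
  daily_series(as.Date(sprintf("%d-01-01", year)) + seq_len(n) - 1,
               rep(value, n), variable = "temperature")
}

# A fake posterior fit with fixed coefficient draws, for deterministic tests
# of the scoring and prediction rules.
fixed_fit <- function(draws_matrix) {
  structure(list(draws = list(draws_matrix),
                 coef_names = colnames(draws_matrix),
                 rhat = rep(1, ncol(draws_matrix)), converged = TRUE,
                 accept_rate = 1, chains = 1, steps = nrow(draws_matrix),
                 burn_in = 0, prior_sd = 100, seed = 0,
                 model_spec = colnames(draws_matrix), model_id = "fixed"),
            class = "gw_fit")
}

# Brute-force cumulative-departure argmin (independent oracle).
pulse_oracle <- function(q, ref) {
  best_day <- 1L
  best <- Inf
  run <- 0
  for (i in seq_along(q)) {
    run <- run + (q[i] - ref)
    if (run < best) {
      best <- run
      best_day <- i
    }
  }
  best_day
}

# Brute-force median of pairwise slopes (independent oracle).
theil_sen_oracle <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i < j) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  median(slopes)
}
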
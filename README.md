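# greenwave

Streamflow and temperature phenology models of ungulate spring migration.

In snowmelt-driven mountain basins, migratory herbivores such as mule deer
(*Odocoileus hemionus*) track the spring "green wave" of emerging vegetation.
The same warming that starts the green wave swells the rivers draining the
basin — the "spring pulse" — so the onset day of the pulse, read from a
streamgage's daily record, is a watershed-integrated, long-record, real-time
indicator of snowmelt timing. `greenwave` provides a tested pipeline for
asking whether that indicator predicts the onset of spring migration as well
as traditional temperature-derived phenology metrics:

* **Spring-pulse detection** (cumulative-departure method): the pulse day for
  year *j* is the day *i* minimizing the running sum
  `C_i = Σ_{k≤i} (Q_k − Q̄_j)`, with a lagged variant that references the
  previous year's mean flow so it can run in real time.
* **Temperature phenology**: cumulative growing degree day
  `GDD_i = Σ_{k≤i} max(T_k − T_base, 0)` with `T_base = −0.25·latitude + 13`;
  the GDD-180 first-day-of-spring; and the GDD "jerk" — the day the third
  derivative of a fitted logistic `f(t) = Asym/(1 + exp((xmid − t)/scal))`
  peaks, in closed form `xmid + scal·logit(1/2 − √96/24) ≈ xmid − 2.2924·scal`.
* **Trend tests**: Kendall-Theil (Theil-Sen) slopes with Mann-Kendall
  significance (tie-corrected, continuity-corrected) and a lag-1
  autocorrelation pre-check, reported in days per decade.
* **Migration response**: per-herd-year daily 0/1 group-migration state over
  days 1–150, switching on the first day the maximum number of collared
  animals are simultaneously in migration.
* **Bayesian Bernoulli-logit models**: `M_i ~ Bern(θ_i)`,
  `logit(θ_i) = β₀ + Σ β_k x_ki`, diffuse `N(0, sd 100)` priors, MCMC with
  Gelman-Rubin diagnostics, DIC / recall / precision scoring, a Pearson
  `|R| > 0.20` multicollinearity screen, and per-herd-year predicted
  initiation days (first day posterior-median `θ` exceeds 50%) with RMSE and
  period medians/IQRs.
* **Synthetic generators** with known ground truth for every stage, so the
  whole pipeline is testable offline.

The per-herd-year migration summaries for the northern and southern Atlantic
Rim herds (2005–2006, 2008–2010, 2015–2018) ship as a plain-CSV fixture
(`atlantic_rim_herd_years()`).

## Worked example

Migration statistics from the packaged herd-year table:

```r
library(greenwave)
cross_herd_stats(atlantic_rim_herd_years())
#> $initiation_diff_median_days   # median per-year NAR − SAR group initiation
#> [1] 1                          # difference: groups start ~together
#> $displacement_diff_km          # SAR deer migrate a median 20 km farther
#> [1] 20
#> $latest_group_initiation_day   # 2008-05-16 in the NAR herd (leap year)
#> [1] 137
#> $earliest_individual_day
#> NAR SAR
#>  72  20                        # earliest SAR individual left on Jan 20
```

An end-to-end synthetic run — generate nine years of hydrographs and
temperatures, detect the pulses, build covariates, generate herd responses
from a known model (`β_Dsm = 0.25`), fit, and predict:

```r
b <- run_pipeline(list(seed = 1,
                       mcmc = list(chains = 3, steps = 5000, burn_in = 1000),
                       model_specs = list(dsm = c("dsm_synthetic", "herd"))))
b$model_table
#>  model               spec      dic    recall precision converged
#>    dsm dsm_synthetic+herd 262.4817 0.9438669 0.9341564      TRUE
summary(b$fits$dsm)
#>            coef   mean     sd   q2.5    q50  q97.5 rhat excludes_zero
#> 1   (Intercept) -6.039 0.5634 -7.169 -6.021 -5.020    1          TRUE
#> 2 dsm_synthetic  0.470 0.0412  0.396  0.468  0.557    1          TRUE
#> 3          herd -0.868 0.3319 -1.564 -0.851 -0.237    1          TRUE
head(b$predictions)
#>  herd year observed_day predicted_day
#>   NAR 2001          120           118
#>   NAR 2002          131           134
#>   NAR 2003          127           137
#>   ...
b$rmse_days
#> [1] 3.95
```

The snowmelt covariate's coefficient is recovered with a tight credible
interval excluding zero, the day-level classification reaches recall/
precision ≈ 0.94/0.93, and predicted initiation days land within about four
days RMSE of the generator's ground truth. (The fitted `dsm_synthetic`
coefficient exceeds the generating 0.25 because step responses concentrate
the transition; the crossing day, which drives prediction, is what is
calibrated.) For real data, point `run_pipeline(list(mode = "files", ...))`
at NWIS daily-values RDB exports, a basin-mean temperature CSV, and a
per-animal migration CSV.

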
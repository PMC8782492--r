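---
title: "Methods: linking snowmelt and temperature phenology to ungulate spring migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking snowmelt and temperature phenology to ungulate spring migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mule deer herds in snowmelt-driven mountain basins migrate in spring along the
"green wave" of newly emerging vegetation. The same warming that starts the
green wave melts the snowpack, so rivers draining these basins swell in an
abrupt, sustained "spring pulse" whose onset day is a watershed-integrated
indicator of snowmelt timing. Streamgages have daily records spanning many
decades and report in near real time, which makes the spring pulse an
attractive predictor of migration timing compared with satellite greenness
(short record, cloud latency) or temperature-derived phenology (short gridded
record, and some metrics need the whole curve before they can be computed).

`greenwave` implements that comparison as a reusable pipeline: detect the
spring pulse from daily streamflow, compute temperature-derived spring
metrics, test all annual series for temporal trends, fit Bayesian
Bernoulli-logit models of daily group-migration state on these covariates,
and turn the fitted model into a daily probability-of-migration predictor.

## Covariates

**Spring pulse (`Dsm`).** Following the cumulative-departure convention, the
pulse onset for a year is the day `i` minimizing `C_i = sum_{k<=i} (Q_k -
Qbar)`, with `Qbar` the calendar-year mean flow. Ties break to the earliest
day. We take the day *of* the minimum (the last below-mean day before
sustained snowmelt flow); some authors report the day after, available as
`convention = "min_plus_one"`. Printed pulse days in the source data cannot
disambiguate the two, so the default is fixed and documented rather than
inferred. The daily covariate is `Dsm_ji = J_ji - pulse_day_j`, the signed
number of days since the pulse. A lagged variant (`Dpsm`) references the
*previous* year's mean flow, which is already known while year `j` unfolds,
making it usable for real-time forecasting.

**Gap policy.** Daily-value records have occasional gaps. Gaps of at most
`max_gap = 7` consecutive days are filled by linear interpolation
(`zoo::na.approx`); longer gaps, or gaps touching a year boundary, exclude
the year. Seven days keeps interpolation well below the duration of the
pulse rise; the source records had only limited gaps and no published rule.

**Growing degree day (`GDD`).** Daily growing degree units `GDU_i = T_i -
T_base` accumulate from January 1, with `T_base = -0.25 * latitude + 13`
(degrees C). The latitude is a single user-supplied basin-representative
value because one basin-level GDD series is wanted, not one per grid cell.
Negative GDUs are floored at zero by default: winter temperatures here sit
well below `T_base`, and an unfloored curve would decrease through winter
and break the monotone-sigmoid assumption used below. The literal unfloored
accumulation remains available (`floor_at_zero = FALSE`). The first day of
spring is the first day the cumulative sum strictly exceeds 180 degC day.

**GDD jerk (`JERK`).** A three-parameter logistic `f(t) = Asym / (1 +
exp((xmid - t)/scal))` is fitted to each annual GDD curve by least squares
(self-starting `SSlogis`, with a deterministic fallback start and
`scaleOffset = 1` so exact, zero-residual curves also converge). The jerk
day is the day the third derivative of `f` is maximal — the moment spring
warm-up accelerates fastest. The critical points of `f'''` satisfy `(1 -
2s)(12 s^2 - 12 s + 1) = 0` in `s = logit^{-1}((t - xmid)/scal)`, giving the
closed form `jerk = xmid + scal * logit(1/2 - sqrt(96)/24) ~= xmid -
2.2924 * scal`. One subtlety: `f'''` is symmetric about `xmid`, so an equal
mirror peak exists at `xmid + 2.2924 * scal` where the curve flattens. The
jerk is defined on the rising branch (warm-up accelerating), and the numeric
cross-check maximizes only over `t <= xmid`; an unrestricted grid search
would pick between the two equal peaks by floating-point accident.

## Trend analysis

Annual series (pulse day, GDD-180 day, jerk day) are tested with the
Kendall-Theil (Theil-Sen) slope — the median of all pairwise slopes, with
the median of an even count taken as the midpoint of the central pair — and
the Mann-Kendall `S` statistic with tie-corrected variance and continuity
correction. Slopes are also reported per decade (10 times the per-year
slope), the customary unit for runoff-timing trends. Before testing, the
lag-1 sample autocorrelation is checked against the white-noise bound
`1.96/sqrt(n)`; a flagged series is annotated, not suppressed, because no
remediation procedure is part of the design and the flag is what a reader
needs. The specific autocorrelation check is this package's choice.

## The migration response

Per-animal records give a start and end day of spring migration. A herd's
*group initiation day* for a year is the first day the maximum observed
number of collared animals are simultaneously in migration ("in migration
on day i" means `start <= i <= end`, both ends inclusive). The daily binary
response is 0 before that day and 1 from it through day 150 — the end of
May in common years, covering the latest observed phenology (147), pulse
(119) and group initiation (137) days. Day 150 is a parameter (`horizon`);
the alternative reading of "the first 151 days" would set it to 151, and the
explicit day number was preferred. Years with a single collared animal are
retained; the group rule degenerates gracefully to that animal's start day.

## The Bernoulli-logit model

For day `i`, `M_i ~ Bernoulli(theta_i)` with `logit(theta_i) = beta_0 +
sum_k beta_k x_ki`, where the `x_k` are any subset of {daily temperature,
GDD, JERK, Dsm per gage, Dpsm, herd dummy} (NAR = 0, SAR = 1; the dummy
coding is this package's choice). Covariates enter unstandardized so
coefficients stay on raw day/degree scales. Priors are independent
`N(0, sd = 100)` for every coefficient — the "precision 1e-4"
parameterization of a diffuse normal; the alternative literal reading
(`1/sigma = 1e-4`, sd 1e4) is also diffuse and the choice is
inconsequential at these sample sizes.

**Sampler.** The posterior is explored by a joint random-walk Metropolis
sampler whose Gaussian proposal is the maximum-likelihood Fisher covariance
scaled by `2.38^2/K`, with chains started at the MLE jittered by one
proposal draw. For a logistic posterior, which is smooth and close to
Gaussian at these sample sizes, this mixes rapidly (acceptance near the
0.23–0.44 optimum, split-chain R-hat about 1.001 in the test suite's
fits). The Gibbs scheme used in the original analysis is one valid kernel
among many; the model, priors, chain count and burn-in are what define the
inference, and those are reproduced. Convergence is summarized by the
Gelman-Rubin statistic per coefficient (via `coda`), with the fit flagged
when any R-hat exceeds 1.1. A unit test cross-checks posterior means and
spreads against an independent Gibbs sampler (JAGS) and against the glm MLE
on the same data.

**Scores.** Models are compared by DIC `= Dbar + pD`, `pD = Dbar -
D(beta_bar)`, deviance `= -2 log L`, and by posterior-predictive recall
`TP/(TP+FN)` and precision `TP/(TP+FP)`, where a day is predicted positive
when its posterior-median probability exceeds 0.5. The 0.5 threshold is
stated for the prediction rule and is reused for classification as the
natural reading. Because the logit link is monotone, the median probability
exceeds 0.5 exactly when the median linear predictor exceeds 0, which is
how it is computed. Scoring uses at most 3000 evenly thinned pooled draws;
the comparison table is ordered by highest precision, then highest recall,
then lowest DIC. Multicollinearity is screened by pairwise Pearson `|R| >
0.20` between covariates before multi-covariate models are interpreted.

**Prediction.** For one herd-year, the predicted initiation day is the first
day (through the horizon) whose posterior-median probability exceeds 50%.
Predicted-versus-observed agreement is summarized by RMSE, and long-record
predictions by per-period medians and interquartile ranges (default periods
1943–1959, 1960–1979, 1980–1999, 2000–2018).

## Synthetic data and what it does (not) show

Every stage is testable without external data through generators with known
ground truth:

* **Temperature**: a sinusoid (default mean 6 degC, amplitude 12 degC, phase
  day 105 so the minimum falls in mid-January, iid noise sd 2 degC) — a
  caricature of a cold-desert basin at latitude 41 N that produces a
  realistic GDD rise in April–June.
* **Hydrograph**: baseflow (2 units) plus a pulse of magnitude 40 that rises
  linearly to full over 15 days — `r(k) = (k+1)/15`, so the onset day itself
  already carries signal — then recedes exponentially (rate 0.03/day), with
  multiplicative lognormal noise (sd 0.05 by default). The ramp-plus-
  recession shape is a modeling choice made for an unambiguous ground-truth
  onset. Under 10% noise the day whose flow first clears the annual mean can
  dip back below it, so detection is occasionally one day late; the
  noiseless detector always lands within `[onset - 2, onset]`.
* **Responses**: daily probabilities from a known coefficient vector
  (default `beta_0 = -5`, `beta_Dsm = 0.25`, `beta_herd = -0.25`, i.e. a
  50% crossing 20 days after the pulse, matching the observed two-to-three
  week snowmelt-to-migration lag and the fitted `Dsm` magnitude). Two
  modes: iid daily Bernoulli draws (model-consistent rows, for parameter
  recovery) and first-success steps (structure-consistent monotone
  responses, for end-to-end tests).

Default scale mirrors the study: nine years, two herds, pulse onsets in
days 90–125. The generators deliberately omit features of real data:
streamflow diversions and regulation, autocorrelated weather, inter-annual
snowpack memory, observation error in collar-derived start/end days, and
herd-size variation. Passing tests therefore demonstrate that the
estimators and the inference machinery are correct and well calibrated
under the stated model — not that the model is adequate for any particular
basin. The real-data workflow (NWIS RDB exports, a basin-mean temperature
series) uses exactly the same functions.

## Numerical choices

* Ties in the pulse detector and in group initiation break to the earliest
  day; `which.min`/`which` provide this directly.
* "Exceeds 180 degC day" and "probability exceeds 50%" are strict
  inequalities.
* The finite-difference oracle for the jerk uses step `h = 0.02 * scal`,
  balancing truncation bias (which grows with `h`) against roundoff
  cancellation in the third difference (which explodes as `h` shrinks);
  with a fixed small `h` the oracle is wrong for large `scal`.
* Generators restore the caller's RNG state; every stochastic function
  takes an explicit seed and chain seeds are derived reproducibly from it.
* Test and acceptance runs use 3 chains of 5000 retained steps (1000
  burn-in) and 18–20 synthetic herd-years; these sizes give Monte-Carlo
  error well below the tolerances checked while keeping runs short. The
  20000-step default of `fit_bayes_logistic()` matches the original
  analysis settings.

## Limitations

* The pulse detector presumes a snowmelt-dominated annual hydrograph; in
  diversion-affected or rain-dominated records the cumulative-departure
  minimum may not correspond to snowmelt onset.
* The logistic model treats days as conditionally independent given the
  covariates, while the constructed response is a monotone step; the model
  is calibrated for the crossing day, not for day-to-day dependence.
* Herd-level initiation from collared subsets is a proxy; years with very
  few collars carry the same weight as well-sampled years.
* Real-data replication of the original numbers requires NWIS and gridded
  temperature downloads and is wired but not bundled.
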
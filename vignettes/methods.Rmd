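---
title: "Methods: indicators, predictability and multi-horizon forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indicators, predictability and multi-horizon forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`foodcast` studies how far ahead the daily sub-national prevalence of
insufficient food consumption can be forecast, and what limits that
forecastability. This vignette is the package's account of its methods: the
indicator construction, the permutation-entropy predictability analysis,
the forecasting and evaluation design, and the synthetic-data generator
that makes the whole pipeline testable without operational survey data. It
also records the numerical conventions and the design decisions that were
genuinely open.

## 1. From household interviews to daily prevalence series

**Food Consumption Score.** Each interviewed household reports how often,
during the previous 7 days, it consumed items from eight food groups
(staples, pulses, vegetables, fruit, meat/fish, milk, sugar, oil). The FCS
is the weighted sum of these frequencies; weights reflect nutritional
density. The package defaults to the standard WFP weights
(2, 3, 1, 1, 4, 4, 0.5, 0.5) and thresholds 21 and 35: a household is
*poor* if FCS ≤ 21, *borderline* if 21 < FCS ≤ 35 (both bounds inclusive
above), *acceptable* otherwise. "Insufficient food consumption" means poor
or borderline. Country programmes use slightly different thresholds, so
both weights and thresholds are plain arguments of `fcs_scheme()`.

**Reduced Coping Strategy Index.** The companion indicator sums the 7-day
frequencies of five food-based coping behaviours with severity weights
(1, 2, 1, 3, 1 by default); rCSI ≥ 19 (inclusive) flags crisis-or-above
coping. The prevalence of crisis coping enters the forecasting model as an
endogenous driver.

**Rolling weighted prevalence.** A single day's interviews in one area are
too few for a stable estimate, so the prevalence at day *t* is the weighted
share of flagged households among all those interviewed during the previous
*d* days. We read "previous *d* days" as the half-open window (*t−d*, *t*]:
day *t*'s interviews count toward day *t*, and drop out *d* days later,
which is the natural convention for a daily-updated trailing window. The
household weight is the product of its population weight (correcting
over/under-sampled areas) and its demographic weight (correcting selection
bias); the estimator is invariant to rescaling all weights. *d* is a
per-country parameter; the default is 28 days, a typical monthly survey
cycle. Days whose window contains no interviews are missing; interior gaps
are filled by linear interpolation between the nearest observed neighbours
(`zoo::na.approx`). Leading and trailing gaps are left missing —
interpolation is defined only *between* observations, and we do not
extrapolate.

## 2. Intrinsic predictability via permutation entropy

To ask whether the prevalence series can be forecast *from its own history
alone*, we use a model-free complexity measure. Every window of *m* values
spaced τ apart is mapped to the permutation that sorts it ascending
(ordinal pattern). The permutation entropy is the Shannon entropy of the
pattern distribution, H = −Σ p log p, normalized by log *m*! so H ∈ [0, 1];
the predictability is χ = 1 − H. A monotone (fully regular) series has one
pattern and χ = 1; a series whose patterns are uniform noise has χ = 0.
Because the symbolisation only uses rank order, χ is invariant under
positive affine transforms — areas with very different prevalence levels
are comparable.

Conventions: ties are broken by temporal order (the earlier of two equal
values ranks lower — the standard stable-argsort convention; it keeps the
mapping deterministic). Natural logarithms are used; the base cancels under
normalization. The default embedding is m = 3, τ = 1: with windows as short
as 10 days, m! must stay small relative to the number of patterns per
window, and m = 3 (6 patterns) is the largest embedding that is reasonably
sampled at that scale; m is configurable in 2..7 with a warning when m!
exceeds the pattern count of the smallest window.

`predictability_profile()` follows the windowed design: for each window
length L = 10, 11, …, 100 days it draws 1000 random window placements per
area series (without replacement when enough placements exist), computes
normalized H on each window, and aggregates the mean and interquartile
range of χ across all windows and areas. Internally the pattern sequence is
computed once per series and window tabulations are taken from cumulative
counts, so the profile costs O(N + samples) per window length.

## 3. Drivers and the lagged design matrix

The forecasting model uses information from three driver domains plus the
survey indicators themselves:

* **Conflict**: fatalities from event records, summed over the same
  trailing *d*-day window as the prevalence (so both sides of the model
  aggregate time identically).
* **Markets**: monthly staple prices, normalized per market (by the
  market's own mean up to a training cutoff — leakage-safe — or by its
  first value) and averaged across an area's markets, carried forward to
  daily resolution.
* **Weather**: dekadal (10-day) rainfall and NDVI. Anomalies use the
  percent-of-average convention — 100 × (trailing sum ÷ baseline sum over
  the same dekads of the year) — over 1-month (3 dekads) and 3-month
  (9 dekads) windows for rainfall and a single dekad for NDVI (vegetation
  already integrates past rainfall). 100 means a normal season. Dekadal
  values are repeated across the days of their dekad.
* **Ramadan**: the number of days of the window (*t−d*, *t*] inside a
  Ramadan observance period — consumption patterns change during Ramadan,
  and the counter mirrors how the survey window straddles it.
* **Statics and calendar**: population, area size, latitude/longitude,
  waterways, and the day/month/year of the *forecast* date.

**Feature screening.** Within the weather category (the only category with
several collinear candidates) pairwise Pearson correlations are computed on
the native dekadal resolution — daily expansion would replicate each value
ten times without adding information — and while any pair has |r| > 0.45,
the member of the strongest-correlated pair with the larger mean absolute
correlation to the other survivors is dropped (ties by name order). The
0.45 threshold is deliberately conservative. Pruning is idempotent. The
surviving features then get a variance-inflation-factor check
(VIF = 1/(1−R²) from regressing each on the others, flagged at ≥ 3).

**Design matrix.** One design underlies all horizon models: for each
(area, reference date) the features are lagged values of the target
prevalence and rCSI prevalence (lags 0–30 by default) and of each driver
(lags 0, 7, 14, 30), plus statics. A horizon-*h* row adds the target *h*
days after the reference date and the calendar identifiers of that future
date. By construction no feature is dated after the reference date; rows
with missing target are dropped, rows with missing features are kept —
the boosted-tree learner routes missing values natively, which matters
operationally when driver feeds arrive late.

## 4. Forecasting and evaluation design

**Thirty models.** The learner (XGBoost, squared-error objective) does not
produce multi-output forecasts, so one model is fitted per horizon
h = 1…30, each trained only on its own horizon's rows.

**Time-ordered validation.** Within a split's training region (everything
whose target precedes the test month), the first 80% of rows in time order
train each hyper-parameter candidate and the last 20% validate it; the
number of boosting rounds comes from early stopping on validation RMSE
(default patience 25, cap 300 rounds). The winning configuration is refit
on the full training region — whether to refit after validation was an
open choice; refitting uses all available data and is the default, and
`refit = FALSE` preserves the validated model instead. The default search
grid is depth {3, 5, 7} × learning rate {0.05, 0.1} × row subsampling
{0.8, 1.0}; feature-lag presets can be searched as an additional grid
column (a bounded form of feature selection). All learner randomness is
seeded; identical seeds give bit-identical models.

**Monthly test splits.** Evaluation uses k (default 5) disjoint calendar
months at the series tail. For each split and horizon *h*, predictions are
issued from every admissible origin: reference dates before the test month
whose target (origin + *h*) falls inside it — *h* origins per area for
horizon *h*. Every origin's information set predates the test window, so
the evaluation is leak-free by construction (corrupting all data from the
test-month start onward leaves every test prediction bit-identical), while
long horizons are scored on many more points than a single-origin design
would give. Predictions are clipped to [0, 1] (the target is a prevalence).

**Persistence baseline.** The naive forecast from origin *o* is the last
observed value at or before *o*, for every horizon. R² (1 − SSE/SST with
the test-cell mean) and MSE are computed per split × horizon, pooling
areas; ΔMSE = MSE<sub>naive</sub> − MSE<sub>model</sub> > 0 means the model
beats persistence. Per-area scores are available from the row-level
predictions for diagnostics. Pooled-versus-per-area R² was an open choice;
pooled is the default because each split/horizon cell should yield one
number.

**Learning curves.** `learning_curve()` re-runs the full train/test cycle
on nested data subsets — shorter histories at fixed area count, fewer areas
at fixed history length — and reports mean ± sd of ΔMSE across splits at
weekly horizons (7/14/21/28 days). Two design details make the size effect
measurable at package scale: subsets keep the *most recent* days so all
variants share the same test months, and the area-count family can be
scored on a common area subset (`eval_areas`), so that skill differences
reflect training data rather than test-set composition. A variant's
training size is its count of area-day target observations before its
earliest test month.

## 5. The synthetic-data generator

The generator exists so that every stage — indicator construction,
predictability, screening, forecasting, evaluation — can be exercised and
tested end-to-end with known ground truth. It emulates a Yemen-like study:
20 first-level areas observed daily for 1340 days (the defaults), with
latent prevalence mostly inside the 20–60% band.

**Latent prevalence.** On the logit scale, each area-day combines: an
intercept (−0.75) and a static per-area offset (sd 0.2); lagged driver
effects; and AR(1) noise (ρ = 0.97, innovation sd 0.06 — slow mixing, so
the series is smooth at short range but drifts over weeks, which is what
makes persistence strong at h = 1 and weak at h = 28). The driver effects
are: centred log(1+·) of the trailing 28-day fatality sum (+0.25); the
1-month rainfall anomaly as a linear term (−0.15) *and* a drought hinge
+0.7 × max(0, 1 − anomaly/100) — deficits raise food insecurity, surpluses
do not symmetrically lower it; the log normalized price (+0.45); a
conflict × price interaction +0.45 × (centred log fatalities) ×
max(0, log price) — conflict bites harder when staples are expensive; and a
Ramadan term (−0.25 × window share). The hinge and interaction are there
deliberately: a purely additive smooth surface is learnable from a few
hundred rows, which would make forecast skill insensitive to training-set
size; the nonlinear shared structure gives larger datasets something real
to buy. Each driver acts at a generator-side lag (fatalities and prices 30
days, rainfall 60 days), so drivers observed at a forecast origin genuinely
carry signal about the 30-day-ahead target.

**Drivers.** Fatalities are Poisson (0.5/day) with episodic bursts
(geometric duration, mean 10 days, rate 15/day, entered with probability
0.01/day) — conflict is episodic, not white noise. Dekadal rainfall is
gamma-distributed around a per-area seasonal mean curve (base 8 mm +
amplitude 55 mm, peaking in dekad 22, per-area wetness multipliers in
0.7–1.3); the curve itself is the historical baseline, so anomalies are
exactly 100 in expectation. NDVI responds to the previous three dekads of
rainfall plus noise. Prices follow a per-market geometric random walk with
weak drift (0.003/month), volatility 0.04 and occasional upward jumps —
prices fluctuate and shock rather than trend strongly, matching settings
where no common secular trend dominates the series. Ramadan dates are the
2018–2023 Gregorian intervals. All sub-streams derive deterministically
from one integer seed.

**Surveys.** Each area-day yields `households_per_day` interviews (default
25, a desk-scale stand-in for the ~150-per-stratum operational target). The
household's class is drawn first — Bernoulli on the latent prevalence — and
its food-group frequency vector is then drawn uniformly from the integer
vectors consistent with that class under the configured scheme (batch
rejection sampling). This makes class marginals exact by construction, so
indicator recovery is exactly testable: with 1000 households/day the
rolling estimator recovers the latent path within twice the binomial
standard error. Coping frequencies are drawn the same way conditional on a
crisis flag (probability 0.7 given insufficient consumption, 0.15
otherwise), coupling the rCSI prevalence to the latent path. The
post-stratification weight law is not pinned down by any public source, so
it is a free configuration choice: lognormal with median 1 and log-sd 0.3.
An optional `gap_fraction` removes whole area-days to exercise the
interpolation.

**What the generator does not emulate.** No spatial correlation between
areas beyond shared seasonality; no panel structure or respondent-level
autocorrelation; no mode or selection bias beyond random weights; no
secular trends or regime shifts; stationary driver laws. Tests passing on
this generator therefore demonstrate the pipeline's correctness and the
qualitative driver-coupling mechanisms, not performance on real survey
data — real series carry nonstationarities and biases this generator
deliberately leaves out.

**Calibration.** The default coefficients were calibrated once, by
simulation, to the stated working band (≥ 90% of latent values in
[0.15, 0.65] under default settings) while keeping each mechanism's
contribution plausible; they are study conditions, not fitting targets.

## 6. Numerical choices and degenerate inputs

* Ordinal patterns: stable ranking (ties by temporal order); pattern ids
  are computed vectorised from pairwise comparisons; 0·log 0 = 0.
* `predictability()` refuses H outside [0, 1] — a guard against passing
  unnormalized entropies.
* Rolling sums use a fixed-window moving dot product (`stats::filter`),
  with exact cumulative sums for the ramp-up days; the estimator matches a
  brute-force per-day recomputation to 1e-12.
* Constant series have undefined correlations; `correlation_prune()`
  treats them as 0 with a warning. Exactly collinear features get VIF = ∞
  and are flagged. Zero-variance test cells give R² = NA with a warning.
* Grid ties in validation go to the first candidate in grid order;
  identical seeds reproduce every fit bit-for-bit (`nthread = 1`).
* Empty survey input yields an empty typed series; all-missing series and
  out-of-range frequencies are hard errors naming the offending field or
  rows.

## 7. Problem sizes used by the test suite

The package's own checks run at deliberately modest scales chosen to keep
the full suite fast while leaving each property clearly measurable: oracle
comparisons on series up to length 50; indicator recovery on 1 area × 80
days × 1000 households/day; the leakage property on 5 areas × 400 days; the
skill benchmark on 20 areas × 1300 days with 3 monthly splits, horizons
{1, 28} and a two-point hyper-grid; the learning curves on a 16-area ×
1300-day base with four nested sizes per family. The acceptance script
re-runs the same designs from scratch under a caller-supplied seed.

## 8. Known limitations

* The learning-curve monotonicity is a weak effect measured on 4 sizes; a
  Spearman rank correlation over 4 noisy points can occasionally come out
  negative under an unlucky seed even though the underlying trend is
  positive (it is positive in the large majority of seeds tested during
  development).
* The evaluation's "many origins per horizon" design concentrates test
  information at long horizons; h = 1 cells rest on one origin per area
  per split and are correspondingly noisier.
* Dekadal driver values are treated as available from the first day of
  their dekad; operationally they arrive after the dekad closes. The
  design-side lags absorb this in practice, but users connecting real
  feeds should lag weather features accordingly.
* Forecasts of the drivers themselves are out of scope; all forecasts
  condition on drivers observed up to the origin.
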
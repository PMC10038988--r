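# foodcast

How far ahead can food insecurity be forecast? `foodcast` is an R package
for studying the *forecastability* of the daily prevalence of insufficient
food consumption at sub-national level — the key indicator monitored through
continuous household phone surveys in countries facing major food crises. It
is written for quantitative epidemiologists and food-security analysts who
want to reproduce, stress-test or extend this kind of analysis without
access to operational survey microdata: a seeded synthetic-data generator
stands in for the real thing.

The package implements the full analysis pipeline:

1. **Indicator construction.** Each surveyed household gets a Food
   Consumption Score, the weighted sum of its 7-day food-group consumption
   frequencies, FCS = Σ<sub>g</sub> w<sub>g</sub> f<sub>g</sub>, classified
   as poor / borderline / acceptable by thresholds; "insufficient" = poor or
   borderline. The daily area-level prevalence is the post-stratification
   weighted share of insufficient households interviewed during the previous
   *d* days (a rolling window), with interior gaps filled by linear
   interpolation. The reduced Coping Strategy Index (rCSI ≥ 19 ⇒
   crisis-level coping) is built the same way as a companion indicator.
2. **Intrinsic predictability.** Series are symbolised into ordinal patterns
   (Bandt–Pompe) and scored by normalized permutation entropy
   H = −Σ<sub>π</sub> p<sub>π</sub> log p<sub>π</sub> / log m!. The
   predictability χ = 1 − H is profiled over window lengths 10–100 days via
   1000 random window placements per series.
3. **Multi-horizon forecasting.** Thirty horizon-specific gradient-boosted
   tree models (XGBoost) predict prevalence 1–30 days ahead from lagged
   prevalence, lagged rCSI prevalence, conflict fatalities, market prices,
   rainfall/NDVI and their percent-of-average anomalies (screened by |r| >
   0.45 pairwise pruning and a VIF check), a Ramadan window counter, static
   area attributes and calendar features. Validation is time-ordered (first
   80% train / last 20% validate), evaluation uses monthly test blocks at
   the series tail, and every model is benchmarked against the naive
   persistence forecast (the last measured value). Skill is reported as
   per-split R² / MSE and ΔMSE = MSE<sub>naive</sub> − MSE<sub>model</sub>,
   plus learning curves of ΔMSE versus training-set size.

## Worked example

Simulate a 6-area, 700-day scenario, build the prevalence series, profile
its predictability, and benchmark forecasts against persistence on two
monthly test splits:

```r
library(foodcast)
library(dplyr)

cfg <- scenario_config(n_areas = 6, n_days = 700, households_per_day = 20, seed = 42)
sc  <- simulate_scenario(cfg)

prev <- rolling_prevalence(sc$surveys, d = 28) |> interpolate_gaps()
predictability_profile(prev, window_lengths = c(10, 30, 60, 100),
                       n_samples = 500, seed = 42)
#> # A tibble: 4 × 5
#>   window_length mean_chi    q25   q75 n_windows
#>           <int>    <dbl>  <dbl> <dbl>     <int>
#> 1            10   0.377  0.166  0.498      3000
#> 2            30   0.192  0.0842 0.258      3000
#> 3            60   0.120  0.0632 0.157      3000
#> 4           100   0.0972 0.0614 0.133      3000
```

Predictability starts low (χ ≈ 0.38 over 10-day windows) and decays towards
noise levels as longer stretches of history are considered — the series'
own past carries little long-range information, which motivates bringing in
the secondary drivers:

```r
asm    <- assemble_design(sc, horizons = c(1, 7, 28))
splits <- make_splits(asm$design, k = 2)
ex <- run_forecast_experiment(asm$design, splits, horizons = c(1, 7, 28),
        grid = tibble(max_depth = 3, eta = 0.1, subsample = 0.8),
        nrounds_max = 150, seed = 42)
tidy(ex) |> select(split_id, horizon, r2_model, r2_naive, mse_model, mse_naive, n_test)
#> # A tibble: 6 × 7
#>   split_id horizon r2_model r2_naive mse_model mse_naive n_test
#>      <int>   <int>    <dbl>    <dbl>     <dbl>     <dbl>  <int>
#> 1        1       1    0.994    0.994  0.000116  0.000126      6
#> 2        1       7    0.936    0.920  0.00122   0.00154      42
#> 3        1      28    0.699    0.355  0.00581   0.0124      168
#> 4        2       1    0.994    0.993  0.000117  0.000138      6
#> 5        2       7    0.975    0.946  0.000528  0.00113      42
#> 6        2      28    0.851    0.698  0.00377   0.00766     168
```

At one day ahead the model and the naive forecast are nearly tied (R² ≈
0.99 both — prevalence from a 28-day rolling window barely moves overnight).
At 28 days ahead the driver-informed model explains 70–85% of the variance
where persistence explains 36–70%, and its MSE is roughly half the naive
MSE: the advantage of secondary information grows with the horizon.
`autoplot(ex)` and `autoplot(ex, metric = "delta_mse")` draw the
per-horizon skill distributions; `learning_curve()` re-runs the experiment
on nested data subsets to chart skill against training-set size.

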
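# gaitcog

Temporal gait characteristics from shank-worn inertial sensors, signal
complexity, and their link to cognition in midlife cohorts.

Gait speed and stride-timing regularity are among the most promising
non-invasive markers of later cognitive decline, and middle-aged adults
with uncomplicated Type 2 Diabetes Mellitus (T2DM) are a key at-risk group.
`gaitcog` implements the full analysis chain that takes raw shank motion
signals recorded during 20 m walking tasks (normal pace, fast pace, and a
cognitive dual task) to per-walk temporal gait parameters, stride-time
variability and a multiscale-entropy complexity index, and then relates
those gait variables to global cognition (MoCA) with both multivariable
linear regression and a small sigmoid neural network, validated by mean
absolute error under repeated 80/20 hold-outs.

Because raw clinical recordings of this kind are rarely shareable, the
package ships a first-class synthetic-data module: a stride-waveform
simulator with exact ground-truth event timestamps and a cohort generator
whose group-level parameter distributions and gait-cognition coupling
emulate a 138-participant midlife T2DM/control study design. Every
downstream stage is tested against that ground truth.

## The analysis chain

1. **Preprocess** (`preprocess_recording()`): trim to the walking task,
   down-sample to 200 Hz, median filter (window 5), 4th-order Butterworth
   low-pass applied forward–backward (zero-phase; default cutoff 10 Hz).
2. **Gait events** (`detect_gait_events()`): label local extrema of the
   smoothed sagittal-plane signal as toe-off (TO), max swing velocity
   (MSV) and heel strike (HS); each dominant positive peak is an MSV, its
   flanking troughs are TO (before) and HS (after).
3. **Temporal parameters** (`stride_intervals()`, `summarize_walk()`):

   ```
   swing(n)  = HS(n)   − TO(n)
   stance(n) = TO(n+1) − HS(n)
   stride(n) = MSV(n+1) − MSV(n)
   ```

   The turning artifact midway through the 20 m walk is removed by
   deleting swing/stance/stride values deviating more than two sample
   standard deviations from their series mean
   (`remove_turn_artifact()`). Velocity is 20 m divided by the total
   walking time; stride-time variability is `CoV = 100·SD/mean`.
4. **Complexity** (`mse_curve()`, `complexity_index()`): coarse-grain the
   unsmoothed 200 Hz signal at scales τ = 1…40, compute sample entropy
   (m = 2, tolerance r = 0.2 of the scale-1 SD, Chebyshev distance,
   self-matches excluded) at every scale, and integrate the curve — the
   area is the complexity index.
5. **Cohort statistics** (`compare_groups()`, `adjusted_effect()`,
   `screen_correlations()`): Shapiro–Wilk-gated t / Mann–Whitney group
   comparisons, OLS group effects adjusted for age, sex, BMI and
   education, and pooled-cohort Pearson screening of gait variables
   against cognitive scores (|r| ≥ 0.3 selects a variable).
6. **Cognition models** (`validate_model()`, `compare_models()`): MoCA
   predicted from the six walking velocities (3 tasks × 2 feet) by
   least-squares regression and by a fully connected sigmoid network with
   layer widths descending by one (6→5→4→3→2→1), trained with Adam on MSE
   for up to 10,000 epochs with early stopping (patience 50). Both are
   scored by held-out MAE over 20 random 80/20 splits, compared by a
   paired 95% confidence interval.

`run_gait_pipeline()` chains all of this under one master seed and writes
byte-reproducible tables plus a manifest;
`inst/scripts/gait-pipeline.R` is a thin command-line wrapper.

## Worked example

```r
library(gaitcog)
library(dplyr)

# one simulated 20 m walk, through the full chain
walk   <- simulate_walk(stride_params(velocity_mps = 1.35, noise_sd = 0.05), seed = 42)
clean  <- preprocess_recording(walk$recording)
events <- detect_gait_events(clean)
mse    <- mse_curve(clean$signal_raw)
summarize_walk(clean, events, mse)
#> # A tibble: 1 × 11
#>   foot  task   velocity_mps swing_s stance_s stride_s cov_pct complexity n_removed
#>   left  normal         1.08   0.526    0.551     1.08    2.92       20.7         1
```

The summary says: mean swing 0.53 s, stance 0.55 s, stride 1.08 s, a
stride-time CoV of 2.9% (the generator used 3%), and exactly one
pseudo-stride removed — the turn. Velocity uses the full recording clock
(which keeps the turn), so it reads below the generator's straight-line
1.35 m/s; `time_basis = "events"` gives the alternative convention.

```r
# a full cohort: screening and model comparison
cohort <- simulate_cohort(cohort_config(), seed = 1)
wide   <- widen_gait(cohort$gait) |> inner_join(cohort$cohort, by = "subject")
screen_correlations(wide, grep("^velocity_mps_normal", names(wide), value = TRUE),
                    "moca_total")
#>   gait_var                  cog_var        r     n selected
#> 1 velocity_mps_normal_left  moca_total 0.545   138 TRUE
#> 2 velocity_mps_normal_right moca_total 0.536   138 TRUE

vel <- grep("^velocity_mps_", names(wide), value = TRUE)
mlr <- validate_model(wide, vel, model = "mlr", seed = 7)
nn  <- validate_model(wide, vel, model = "nn",  seed = 7)
mlr
#> <validation_report> mlr: MAE 1.094 [95% CI 1.029-1.158] over 20 repeats (n = 138)
nn
#> <validation_report> nn: MAE 1.137 [95% CI 1.066-1.209] over 20 repeats (n = 138)
compare_models(nn, mlr)
#>   model_a model_b mean_diff conf.low conf.high verdict
#> 1 nn      mlr        0.0437 -0.00608    0.0934 ns
```

Normal-walk velocity clears the 0.3 screening threshold; the network does
not outperform the linear model (paired CI covers zero, verdict `ns`) —
on a linearly generated cohort there is nothing extra for it to learn.
The package also ships the reference six-velocity MoCA predictor from a
published midlife cohort:

```r
predict(reference_moca_predictor(), rep(0, 6))
#> [1] 21.2
```

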
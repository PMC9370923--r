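---
title: "From shank signals to cognition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From shank signals to cognition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcog)
```

`gaitcog` turns raw shank motion signals from 20 m walking tasks into
temporal gait parameters, stride-timing variability and a
multiscale-entropy complexity index, and relates those to global
cognition. This vignette explains the model behind each stage, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## The synthetic walk generator

Real shank recordings of this kind (clinical cohorts, wearable IMUs) are
rarely public, so the generator is a first-class, tested module rather
than a test fixture. One gait cycle is modelled as a smooth unit shape on
the cycle phase: a dominant positive Gaussian lobe at mid-swing (the max
swing velocity peak, MSV) flanked by two negative lobes (toe-off, TO,
before; heel strike, HS, after) on a flat stance baseline. This is the
simplest shape with the observed sagittal-plane morphology — one
prominent peak per stride with troughs on either side — and it is
deliberately not a biomechanical model: the waveform carries no physical
unit, no 3-D kinematics, and no sensor model beyond additive Gaussian
noise.

A walk is a sequence of cycles tiling two 10 m halves at the requested
velocity (cycle duration is snapped so an integer number of strides fits
each half, which keeps distance/Σstride-time exactly equal to the nominal
velocity when jitter is zero), separated by a turn. Three choices matter
downstream:

* **Stride-time jitter loads on the stance phase only.** The swing
  (TO→MSV→HS) keeps a fixed absolute duration in every cycle. In real
  gait most stride-time variability sits in stance/double support, and
  keeping the MSV at a fixed offset after TO preserves the telescoping
  identity stride(n) ≈ swing(n) + stance(n) that the event-difference
  formulas imply.
* **The turn is one long pseudo-stride, not extra distance.** Its swing
  is normal; its stance is a stretched pause (default 2.5× the stride
  time) at 0.35× amplitude. Exactly one MSV-to-MSV interval is therefore
  elevated — the signature the two-standard-deviation artifact rule is
  designed to delete — rather than two half-elevated ones.
* **Ground truth is read off the sampled noise-free signal.** Event
  timestamps are snapped to the actual extrema of the rendered template,
  so detector accuracy can be scored in samples without an interpolation
  convention.

The cohort generator draws per-subject stride parameters for three tasks
and two feet from group-level normal distributions anchored to published
temporal gait values for healthy midlife controls versus uncomplicated
T2DM (slower velocity, longer stride times, higher signal noise in the
T2DM group; one source value, a normal-walk velocity SD printed as 1.17
amid SDs of 0.15–0.31, is treated as 0.17). A shared per-subject
"walker" factor (correlation 0.7 across tasks and feet) makes velocities
cohere within subject. Cognition is coupled linearly: continuous MoCA =
23 + 4 × (mean normal-walk velocity) + N(0, 1.5), truncated to [0, 30]
and rounded last (rounding first would attenuate the target
correlation). The 4 points-per-(m/s) linkage with residual SD 1.5 was
chosen once so that the pooled-cohort Pearson correlation between
normal-walk velocity and MoCA lands in the moderate band (≈0.3–0.5) at
n = 138, matching the reported strength of that association; CANTAB
z-scores get a deliberately sub-threshold loading (0.15) so no CANTAB
model is ever selected, and MoCA subdomains are marginal draws only.

What passing tests on this generator do **not** show about real data:
robustness to gait asymmetry, freezing or shuffling patterns, sensor
drift and gravity leakage, imperfect manual trimming, or non-Gaussian
measurement noise. The generator is a correctness harness for the
pipeline's arithmetic, not a validation of the event detector on
pathological gait.

## Preprocessing

The chain is fixed: trim → axis selection → resample to 200 Hz → median
filter (window 5) → 4th-order Butterworth low-pass.

* **Cutoff 10 Hz (configurable).** The cutoff is not dictated by the
  processing description we follow; ambulatory gait energy sits below
  ~10 Hz, so that is the default.
* **Zero-phase filtering.** The Butterworth filter is applied
  forward–backward. A single-pass filter would lag every event timestamp
  by a phase delay and bias the swing/stance/stride differences; whether
  the original analyses filtered once or twice is unknowable from the
  description, and zero-phase is the choice that leaves the formulas
  unbiased. Both the Butterworth stage and the median stage use
  reflection padding so warm-up transients fall outside the data.
* **Resampling** accepts any rate ≥ 200 Hz: integer factors use a
  zero-phase Butterworth anti-alias filter and sample picking (staged so
  no single stage exceeds a factor of 10, keeping the normalized cutoff
  numerically comfortable at 8–20 kHz input rates); rational factors fall
  back to polyphase resampling. Upsampling is refused rather than
  invented.
* **Axis selection** defaults to the highest-variance channel during the
  walk, since only "sagittal plane" is specified for multi-axis files.
* **Trimming is an explicit input** (the original step was manual); the
  pipeline applies a configured window or none.

## Event detection and labelling

Candidate extrema are local maxima/minima with topographic prominence at
least 0.5× the signal SD and pairwise separation at least 0.25 s —
shorter than any plausible half-stride even at fast walk; both are
configurable. Labelling assigns each dominant positive peak as MSV, its
nearest preceding trough as TO and nearest following trough as HS, with
two tie-breaks: equally distant troughs resolve to the earlier one, and
peaks are processed in descending prominence so that a secondary ripple
(e.g. the small stance-baseline bump between HS and the next TO, whose
prominence is inherited from its deep neighbours) finds its flanking
troughs already claimed and is dropped. Incomplete leading/trailing
cycles are dropped; fewer than two complete cycles is an error, not a
guess.

## Temporal parameters and the turn rule

Swing, stance and stride come from the event differences
(swing = HS−TO, stance = next TO−HS, stride = MSV-to-MSV). The turning
artifact is removed by a single-pass rule: within each duration series,
values deviating more than 2 sample standard deviations from the series
mean (both computed once, over the unfiltered series) are flagged. The
rule is deliberately not iterated — one deletion step is what is
described — and sample (n−1) SDs are used wherever a convention is
unstated, the small-sample norm in the gait literature. On simulated
walks the flagged count is almost always exactly the one injected turn
stride, echoing the reported ~1 removed stride per walk.

Velocity is 20 m over the **trimmed recording duration** by default: the
turn is part of the walking clock, since trimming bounds the task but
nothing excises the turn from the timing. The alternative
(`time_basis = "events"`, first-to-last event span) is available; per-foot
velocities are computed per recording, so left and right can differ.

## Multiscale entropy

Sample entropy uses template length m = 2 and tolerance r = 0.2 — the
values established for sagittal-plane gait complexity — with the standard
conventions the description leaves implicit: Chebyshev distance, natural
log, self-matches excluded. The tolerance is fixed once as 0.2× the
scale-1 SD and reused at all scales, which makes the complexity index
exactly invariant to affine rescaling of the input. The scale count is
40: a "series length of 40" reading is untenable for m = 2 sample
entropy (a 40-point series barely defines a single scale), whereas 40
coarse-graining scales matches the description of scale 1 as the original
signal and scale 40 as the maximally granulated one. The curve is
computed on the unsmoothed 200 Hz signal; low-pass filtering first would
delete exactly the high-frequency structure the index is meant to
measure.

Undefined scales — coarse series shorter than 10·m points, or no
matching template pair at length m+1 — are flagged invalid, warned
about, and excluded from the trapezoidal area rather than imputed;
including a ±∞ scale would contaminate the index, and at the default
signal lengths (≥ 750 points, where the index is effectively
length-independent) no scale is invalid anyway.

## Cohort statistics

Group comparisons are normality-gated: Shapiro–Wilk at α = 0.05 on each
group selects Student's t (equal-variance, the classical unpaired test)
or Mann–Whitney U; p-values are two-sided throughout (the source tables
are ambiguous on sidedness, and two-sided is the conservative reading).
Adjusted effects are OLS on the group indicator plus age, sex, BMI and
education. Screening is pooled-cohort Pearson correlation of each gait
variable against each cognitive score; the published selection rule is
printed as "−0.3 ≥ R² ≥ 0.3", which is impossible for a squared
quantity, so it is implemented as |r| ≥ 0.3 (inclusive, configurable) —
the only reading under which the reported 0.33–0.47 velocity
correlations are selectable. No multiple-testing correction is applied
in screening, and none is claimed.

## Cognition models and validation

Both models predict total MoCA from the six walking velocities. The
linear model is ordinary least squares with 95% parameter CIs. The
network is the descending-width architecture: widths n, n−1, …, 2, 1
with sigmoid activation at every node (85 parameters at n = 6), MSE
loss, Adam at its conventional defaults (learning rate 0.001 — only the
optimizer is named in the source), up to 10,000 epochs with early
stopping at patience 50, restoring the best-validation weights.

Three choices were genuinely open:

* **"20-fold validation"** is implemented as 20 repeated random 80/20
  hold-outs (the description couples it to bootstrapping/random
  sampling), not k-fold partitioning; the repeat count and split are
  configurable. The 95% CI on MAE is t-based over the 20 repeats.
* **Standardization is fit on the training split only** by default. The
  source standardizes "all data"; fitting the scaler on the full data
  leaks the held-out distribution into training, so the leakage-free
  variant is the default and `standardize_on = "all"` reproduces the
  literal procedure.
* **Target scaling.** A sigmoid output node cannot reach the 0–30 MoCA
  range, so the target is min–max scaled into (0.05, 0.95) on the
  training split and predictions are inverse-scaled before MAE; the
  margin keeps targets off the saturated tails.

Model comparison pairs the per-repeat MAEs and reports the mean
difference with a t-based 95% CI; "ns" when the interval covers zero. On
linearly generated cohorts the network has nothing beyond the linear
signal to learn, and the verdict is expected (and tested) to be "ns".

## Reproducibility and problem sizes

Every stochastic stage takes a seed; the pipeline derives per-stage seeds
from one master seed by hashing the stage name, so inserting a stage does
not perturb the draws of earlier ones, and two runs with one seed write
byte-identical outputs. The test suite exercises the chain at sizes
chosen to make sampling error negligible relative to each tolerance while
keeping a full run in the minutes range: 100-walk event-recovery batches,
1,000-walk turn-rule batches, 500-replicate CI-coverage simulations at
n = 133, 50-replicate noise-ordering checks at 4,000 samples, and
20-replicate model-comparison experiments on 138-subject cohorts.

## Known limitations

* The waveform is phenomenological; the detector's defaults have only
  been exercised on signals with one dominant peak per stride.
* Spatial parameters (step/stride length) are out of scope — a single
  shank sensor cannot estimate them — as are sensor fusion, automatic
  walk-bout detection and gravity removal.
* The reference six-velocity predictor is carried verbatim from its
  source, including one slope whose printed CI does not bracket its own
  point estimate; only the point estimates are used.
* The MoCA subdomain and CANTAB columns of the simulator are marginal
  emulations for schema completeness, not mechanistic models of those
  tests.
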
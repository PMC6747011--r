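---
title: "Decoding finger positions from surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger positions from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

emgdecode implements a complete research pipeline for continuous
(proportional) myoelectric control of prosthetic fingers: simulation of
calibration sessions, time-domain feature extraction, a regularized lagged
Wiener filter decoder, three-stage model selection, a simulated closed-loop
posture-matching task, and block-wise analytics of short-term user
adaptation. This vignette explains the models behind each stage, the
tunable parameters, the design choices made where the design was genuinely
open, and what the synthetic data can and cannot tell you about real
recordings.

## The decoding model

The decoder estimates the five normalized degrees of actuation (DOAs) of an
anthropomorphic prosthetic hand — thumb rotation, thumb flexion, index,
middle, and the mechanically coupled ring/little pair — from windowed
time-domain features of multi-channel surface EMG. Each output at window
$n$ is a finite-impulse-response filter over the $D$ inputs:

$$y[n] = \sum_{d=1}^{D}\sum_{m=0}^{M-1} h_d[m]\, x_d[n-m],$$

with $M = 6$ lags (a 300 ms filter at the 50 ms window increment). With 16
channels and the default 7-feature bank the lagged input dimensionality is
$16 \times 7 \times 6 = 672$, plus an unpenalized bias column. Weights are
estimated from auto- and cross-correlation matrices,
$(R_{xx} + \lambda I)H = R_{xy}$ with $R_{xx} = X^\top X/N$, solved by a
Cholesky factorization. Scaling the correlation matrices by $N$ (and
penalizing on that scale) keeps the $\lambda$ grid meaningful across
dataset sizes; because $\lambda$ is re-optimized for every fit, the choice
of scaling convention does not change the selected model in practice. The
bias is carried as an unpenalized constant column: the targets live in
$[0,1]$ while the features are standardized to zero mean, so an intercept
is required.

Raw predictions are post-processed with first-order exponential smoothing,
$\tilde y_j[n] = \alpha y_j[n] + (1-\alpha)\tilde y_j[n-1]$, initialized at
$\tilde y_j[1] = y_j[1]$ (the recursion's start is otherwise undefined),
then clipped to $[0,1]$ — the physical actuator limits. Accuracy is scored
with the pooled multivariate $R^2$ across all five outputs, not a
per-output average, so poorly and well decoded DOAs share one denominator.

## Windowing and the feature bank

EMG is processed in sliding windows of 128 ms advanced by 50 ms. Window and
step lengths are realized in samples as `round(ms * fs / 1000)` — 142 and
56 samples at 1,111 Hz — and all downstream grids (glove averaging,
targets, streaming prediction) are defined on this *sample* grid. Defining
the glove grid in nominal milliseconds instead drifts by ~0.4 ms per
window and visibly destroys feature/target alignment over a 900 s session;
this is the package's most important alignment invariant. Windows are
right-aligned (timestamp = window end, the causal convention) and a
trailing partial window is dropped, never padded.

The named feature bank comprises Wilson amplitude, 4th-order
autoregressive coefficients, waveform length, log-variance, and slope sign
change — eight values per channel, while the decoder's input
dimensionality corresponds to seven per channel per lag. Which seven were
used is not derivable from the numbers alone, so the bank is a preset: the
default `"paper7"` uses WAMP, AR1–AR4, waveform length and log-variance
(preserving $D = 672$), and `"full8"` adds slope sign change. Thresholds
for WAMP and SSC are configurable (defaults 10 µV on volt-scaled signals,
and 0); tests always pass thresholds explicitly. Variances and
autocovariances use the population convention (divide by $n$), matching
the correlation-matrix estimation downstream. AR coefficients are computed
by a vectorized Levinson–Durbin recursion over windowed autocovariances
(per-window calls to a generic AR fitter would dominate the runtime of a
session); `stats::ar.yw` serves as the independent oracle in the tests. A
zero-variance window yields all-zero AR coefficients by convention.

Feature columns are standardized by mean subtraction and inverse-SD
scaling with statistics estimated on the training split only;
zero-variance columns are left centered (unit divisor) rather than
producing NaNs.

## Kinematics: glove to DOAs

An 18-DOF data glove stream at 25 Hz is averaged within each processing
window (windows with no glove sample inherit the previous value, a
nearest-sample policy whose error is bounded by the 40 ms glove sampling
interval, below the window length), then mapped to the five DOAs by an
affine map `weights %*% g + offsets`. The calibrated mapping used with the
real hardware is not public; the shipped default is a documented synthetic
stand-in that group-averages flexion sensors per digit and takes thumb
rotation from the thumb-abduction sensor, and any user-supplied 5×18
matrix is accepted. An offset term is included (default 0). Targets are
normalized per DOA to $[0,1]$ with ranges estimated on the training split
only; out-of-range values are clipped.

## Model selection

Calibration runs three stages in a fixed order, each maximizing
validation-set multivariate $R^2$ on a single held-out validation split
(no inner cross-validation):

1. **Sequential forward sensor selection.** Greedy growth from the empty
   set; the stopping rule reads "average performance" as the candidate
   model's validation $R^2$, halting when the best remaining addition
   strictly decreases the running best. Stage-1 fits use a provisional
   $\lambda = 10^{-3}$ (the midpoint of the later grid), recorded in the
   trace. Ties break to the lowest channel index.
2. **$\lambda$ grid search** over exactly
   $\{10^{-6}, 10^{-5}, \dots, 10^{1}\}$; ties to the smaller value.
3. **$\alpha$ line search** over $\{0.00, 0.01, \dots, 1.00\}$. Smoothing
   is a post-process, so the stage smooths the precomputed raw validation
   predictions rather than refitting; predictions are clipped before
   scoring, as at deployment. Ties go to the larger $\alpha$ (less
   latency).

All tie-breaking rules are fixed for reproducibility. After selection the
training and validation sets are merged and the final filter is refit with
the chosen sensors and $\lambda$; feature standardization and target
normalization statistics remain training-only. The returned model carries
a full `SelectionTrace` (every candidate evaluation, per stage), which
also documents that the test split is untouched until final scoring.

## The synthetic session generator

The generator stands in for a participant's neuromuscular system so that
every downstream stage is testable without any data download. Its defaults
are the study conditions: 16 EMG channels (13- and 12-channel amputee
presets), nine calibration motions, 10/10/2 repetitions per motion for
training/validation/test, ~7 s movements separated by 3 s rests, EMG at
1,111 Hz and glove kinematics at 25 Hz.

* **Intent.** Each motion is a minimum-jerk ramp from rest to a stored
  posture template and back (1.5 s ramps — a comfortable volitional speed —
  and a hold at the template). The motion and task-posture templates are an
  editable, synthetic table: the protocol names the shapes but not their
  joint values.
* **EMG.** Amplitude-modulated Gaussian noise: the envelope of channel $c$
  is $(\text{mixing} \cdot \text{intent})_c$ plus a resting baseline of
  0.02 (arbitrary units, so rest is nonzero as in real recordings), and
  the raw signal is the envelope times unit-variance white noise. This is
  the simplest model whose rectified mean tracks the envelope, which is
  all the feature bank needs. Execution noise multiplies the envelope,
  held constant over 0.5 s segments (per-sample jitter would average away
  within a window and would not emulate motor variability).
* **Glove.** The intent passed through the pseudo-inverse of the
  glove-to-DOA map plus 1% Gaussian sensor noise, which guarantees the
  linear kinematic mapping is exactly recoverable. Rest-pose glove values
  are assumed to be exact zeros.
* **Adaptation.** Two per-block mechanisms emulate short-term practice:
  execution-noise SD decays as
  $\sigma_b = \sigma_0 e^{-r\,(b-1)}$, and the mixing columns rotate in a
  fixed random channel-space plane by $\theta\,(b-1)$ radians, drifting
  the envelope covariance structure the way muscle co-activation patterns
  drift with practice.

Everything is a pure function of its parameters and a seed.

What the generator does **not** emulate: biophysically detailed motor-unit
activity, electrode shift, limb-position effects, fatigue spectra,
cross-talk structure, or human reaction time. Passing tests on synthetic
sessions therefore demonstrates the *pipeline's* correctness — alignment,
estimation, selection, scoring — not clinical decoding accuracy on real
muscle signals.

## The virtual posture-matching task

The simulated real-time experiment mirrors the task protocol: 6 blocks ×
18 postures (9 shapes at half and full activation), each posture once per
block in a seeded pseudo-random order; a 3.5 s drive phase and a 1.5 s
evaluation phase with a position update every window increment. The
update interval is one window step (56 samples, 50.4 ms nominal 50 ms), so
the closed loop and batch decoding share one grid and agree bit-for-bit;
the evaluation phase therefore contains 30 samples. (The protocol text
implies 30 = 1.5 s / 50 ms; a printed trial sample count of 300 elsewhere
is inconsistent with that timing and the timing is followed.)

The virtual user corrects its intent toward the target each step by
`gain * (target - observed)` plus block-dependent execution noise —
a stand-in for the compensatory contractions real participants make —
then the EMG → features → filter → smoothing chain produces the observed
hand position. At each trial start the hand resets to fully open and the
decoder state is cleared. During evaluation the intent freezes at its
end-of-drive value (plus execution noise), emulating the "hold the
posture" instruction. Glove mode bypasses the decoder (intent through the
glove map plus sensor noise) and is the task's performance benchmark.

Per trial, MAE is the per-sample mean absolute DOA error, summarized by
the **median** over evaluation samples; the score is
$\max\{0, 1 - \overline{\text{MAE}}/\overline{\text{MAE}_r}\}\times 100\%$
against a Monte-Carlo baseline: the median MAE of $10^6$ uniform random
postures, seeded identically for all virtual subjects. A default gain of
0.7 gives stable, realistic convergence within the drive phase;
gain 1 with a perfect decoder reaches the target in one step.

## Adaptation analytics

Per block, envelopes (windowed mean absolute value, all electrodes
regardless of decoding use) are decomposed by covariance PCA — covariance,
not correlation, because envelopes share units; components get a
deterministic sign (largest-magnitude loading positive). Blocks are
compared by absolute cosine similarity after greedy matching in descending
reference-variance order (the wording "matched in terms of highest cosine
similarity" describes a greedy claim, not an optimal assignment).
Reference-projected variance per block is reported alongside each block's
own explained variance; projection optimality (own $\ge$ projected) is a
theorem and is asserted in the tests.

Early (blocks 1–2) versus late (blocks 5–6) contrasts use a paired test
gated on a D'Agostino–Pearson omnibus normality test of the paired
differences (differences, not groups — the standard choice for paired
designs): paired *t* with Cohen's $d$ (mean difference / SD of
differences) when normal-looking, Wilcoxon signed-rank with the
common-language effect size otherwise. The omnibus test is implemented
in-package from the standard skewness/kurtosis z-statistics (no installed
R package provides it) and is validated against reference values; its
skewness transform requires $n \ge 8$. Subject-level summaries use the
mean or median, themselves gated on normality, and the choice is recorded.
Offline-vs-real-time correlation is Pearson's $r$ with a percentile
bootstrap CI (1,000 iterations; percentile rather than BCa, the scheme
being otherwise unspecified).

## Numerical choices and degenerate inputs

* Ridge systems are solved by Cholesky on the penalized Gram matrix; a
  singular system at $\lambda = 0$ raises an error advising
  $\lambda > 0$.
* Early lag rows are zero-padded rather than dropped so prediction is
  defined from the first window (real-time semantics).
* Batch prediction multiplies row-by-row so that batch and streaming
  decoding share one floating-point accumulation order; a blocked matrix
  multiply can differ in the last ulp.
* Degenerate cases: constant windows give $\ln(\varepsilon)$ log-variance
  and zero AR coefficients; zero-variance feature columns standardize to
  zero; all-zero paired differences short-circuit to a null test result;
  a min = max normalization range and an all-constant $R^2$ denominator
  are errors naming the offending quantity.
* Sessions serialize to a plain-text CSV + JSON dialect (one directory per
  session; all seeds and parameters in `meta.json`).

## Problem sizes used in the tests

The test suite exercises the full study-scale calibration protocol (two
full pipelines: a noiseless user and one at envelope SNR 10 — about 900 s
and 18,000 windows per split), twenty seeded closed-loop sessions of 108
trials for the adaptation trend, 2,000 replicates for the type-I
calibration of the early/late test, and $10^6$-draw Monte-Carlo baselines.
Unit tests use shortened sessions (2 repetitions, 3 s movements) where the
property under test does not depend on scale.

## Known limitations

The linear synergy model makes the decoding problem exactly linear, so
absolute $R^2$ values on synthetic sessions are optimistic; the
acceptance thresholds (0.95 noiseless, 0.9 at SNR 10) are
parameter-recovery checks, not forecasts of real decoding accuracy.
The virtual user has no reaction time, no trajectory planning beyond
proportional correction, and no proprioceptive deficit, so glove-mode
superiority and block-wise improvement are properties of the simulator's
noise schedule rather than biological findings. The statistics module
assumes paired designs with $n \ge 8$ subjects.
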
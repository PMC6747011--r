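# emgdecode

Continuous (proportional) myoelectric control research in R: decode the
positions of individual prosthetic fingers from multi-channel surface EMG,
and quantify how closed-loop practice changes user performance and muscle
co-activation patterns.

The package is aimed at neural-engineering and biomedical-signal
researchers who want a tested, end-to-end, fully simulated replica of a
finger-decoding experiment: calibration data, decoder training and model
selection, a closed-loop posture-matching task, and the adaptation
analytics — with every stage reproducible from a seed.

## The model

The decoder is an L2-regularized, lag-stacked Wiener filter. At window
*n*, each of the *K* = 5 prosthesis degrees of actuation (DOAs) is

> y[n] = Σ_d Σ_m h_d[m] · x_d[n − m],  m = 0 … M−1,

where the inputs *x_d* are time-domain EMG features (Wilson amplitude,
AR1–AR4, waveform length, log-variance; 7 per channel) extracted in
128 ms windows advanced by 50 ms, standardized with training statistics,
and stacked over *M* = 6 lags (a 300 ms filter). With 16 channels the
input dimensionality is D = 672. Weights solve
(R_xx + λI) H = R_xy with correlation matrices R = XᵀX/N, the bias
unpenalized. Predictions are exponentially smoothed
(ỹ[n] = α·y[n] + (1−α)·ỹ[n−1]) and clipped to [0, 1]. Calibration runs
three selection stages on a validation split — sequential forward sensor
selection, a λ grid over 10⁻⁶…10¹, and an α line search over
0.00…1.00 — each maximizing the pooled multivariate R², then refits on
the merged training+validation data.

The virtual posture-matching task presents 18 postures (9 hand shapes at
half/full activation) once per block over 6 blocks (108 trials). Each
trial is scored by the median per-sample mean absolute error (MAE) over a
1.5 s evaluation phase and normalized against a 10⁶-draw Monte-Carlo
random baseline: score = max{0, 1 − MAE/MAE_random} × 100%. A synergy
model of the virtual user (nonnegative channel mixing, block-decaying
execution noise, optional rotation of the mixing columns) generates the
EMG, and the adaptation analytics track block-wise PCA of the EMG
envelopes (absolute cosine similarity of matched components, explained
variance), channel power, output variability, and early-vs-late paired
statistics with normality-gated tests.

## Worked example

Simulate a user, calibrate a decoder, and run a closed-loop session
(shortened calibration for a quick run; defaults reproduce the full
protocol of 10/10/2 repetitions of 7 s movements):

```r
library(emgdecode)

user  <- synergy_model(noise_sd0 = 0.1, adaptation_rate = 0.3, seed = 8)
train <- generate_calibration_session(user, "training",   seed = 1,
                                      reps = 2, movement_s = 3, rest_s = 1)
valid <- generate_calibration_session(user, "validation", seed = 2,
                                      reps = 2, movement_s = 3, rest_s = 1)
test  <- generate_calibration_session(user, "test",       seed = 3,
                                      reps = 2, movement_s = 3, rest_s = 1)

fit <- select_and_finalize(train, valid)
glance(fit)
#> # A tibble: 1 × 6
#>   n_sensors lambda alpha  lags d_lagged validation_r2
#>       <int>  <dbl> <dbl> <int>    <int>         <dbl>
#> 1        12   0.01     1     6      504         0.982

evaluate_offline(fit, test)
#> [1] 0.984
```

Twelve of the 16 channels survive forward selection, giving a 504-column
lagged design; held-out reconstruction accuracy (pooled multivariate R²
over the five DOAs) is 0.98 — high because the synthetic user is exactly
linear. The closed-loop task then shows the practice effect built into
the virtual user (execution noise decaying over blocks):

```r
log <- run_virtual_session(fit, user, mode = "emg", seed = 4,
                           n_baseline_draws = 1e5)
glance(log)
#> # A tibble: 1 × 5
#>   mode  n_trials n_blocks median_mae median_score
#>   <chr>    <int>    <int>      <dbl>        <dbl>
#> 1 emg        108        6     0.0635         84.6

dplyr::summarise(dplyr::group_by(tidy(log), block), mean_mae = mean(mae))
#> # A tibble: 6 × 2
#>   block mean_mae
#>   <int>    <dbl>
#> 1     1   0.108
#> 2     2   0.0956
#> 3     3   0.0764
#> 4     4   0.0563
#> 5     5   0.0526
#> 6     6   0.0472
```

Block-mean MAE falls monotonically from 0.108 to 0.047 as the virtual
user adapts; `early_late_summary(log)` summarizes blocks 1–2 vs 5–6
(here 0.097 → 0.049), and `early_late_comparison()` across a group of
such subjects runs the normality-gated paired test. `autoplot(log)`
draws the learning curve, and `analyze_adaptation(log)` tracks the
block-wise principal components of the EMG envelopes.

## Package tour

| Area | Functions |
| --- | --- |
| Synthetic sessions | `synergy_model()`, `make_intent_trajectory()`, `simulate_emg()`, `generate_calibration_session()`, `virtual_user_command()` |
| Features | `window_config()`, `extract_features()`, `emg_envelope()`, `wilson_amplitude()`, `ar_coefficients()`, `waveform_length()`, `log_variance()`, `slope_sign_change()`, `standardize_features()` |
| Kinematics | `default_doa_map()`, `window_average_glove()`, `glove_to_doa()`, `normalize_doa()` |
| Decoder | `build_lagged_design()`, `fit_wiener()`, `predict()`, `exp_smooth()`, `multivariate_r2()`, `decoder_stream_init()/_feed()` |
| Model selection | `select_and_finalize()`, `sequential_forward_sensors()`, `grid_search_lambda()`, `line_search_alpha()`, `evaluate_offline()` |
| Posture task | `build_protocol()`, `task_postures()`, `run_virtual_session()`, `trial_mae()`, `random_baseline_mae()`, `normalized_score()` |
| Adaptation | `block_pca()`, `match_components()`, `abs_cosine_similarity()`, `variance_explained_by_reference()`, `channel_power_by_block()`, `doa_variability()`, `analyze_adaptation()`, `early_late_comparison()`, `offline_realtime_correlation()` |

See `vignettes/emgdecode-methods.Rmd` for the full account of the models,
parameter choices, and limitations.
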
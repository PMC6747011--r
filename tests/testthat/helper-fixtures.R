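# Shared fixtures, memoized so expensive objects are built once per run.
# Small fixtures use shortened sessions (2 repetitions, 3 s movements);
# the full-scale fixtures reproduce the study-sized calibration protocol
# (9 motions x 10/10/2 repetitions, 7 s movements, 3 s rests).

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_user_small <- function() {
  fx_memo("user_small", function() {
    synergy_model(noise_sd0 = 0.1, adaptation_rate = 0, seed = 11)
  })
}

fx_small_sessions <- function() {
  fx_memo("small_sessions", function() {
    u <- fx_user_small()
    list(
      train = generate_calibration_session(u, "training", seed = 21,
                                           reps = 2, movement_s = 3,
                                           rest_s = 1),
      valid = generate_calibration_session(u, "validation", seed = 22,
                                           reps = 2, movement_s = 3,
                                           rest_s = 1),
      test = generate_calibration_session(u, "test", seed = 23,
                                          reps = 2, movement_s = 3,
                                          rest_s = 1)
    )
  })
}

fx_small_model <- function() {
  fx_memo("small_model", function() {
    s <- fx_small_sessions()
    select_and_finalize(s$train, s$valid, sensors = 1:16)
  })
}

# Full-scale noiseless virtual user and pipeline (parameter recovery).
fx_noiseless_fit <- function() {
  fx_memo("noiseless_fit", function() {
    u <- synergy_model(noise_sd0 = 0, seed = 31)
    tr <- generate_calibration_session(u, "training", seed = 32)
    va <- generate_calibration_session(u, "validation", seed = 33)
    te <- generate_calibration_session(u, "test", seed = 34)
    fit <- select_and_finalize(tr, va)
    list(user = u, fit = fit, test_r2 = evaluate_offline(fit, te))
  })
}

# Full-scale pipeline at envelope SNR 10 (10% multiplicative execution
# noise); the same mixing (seed) also serves as the block-1 state of the
# adapting virtual user used in the closed-loop trend fixture.
fx_snr10_fit <- function() {
  fx_memo("snr10_fit", function() {
    u <- synergy_model(noise_sd0 = 0.1, adaptation_rate = 0, seed = 41)
    tr <- generate_calibration_session(u, "training", seed = 42)
    va <- generate_calibration_session(u, "validation", seed = 43)
    te <- generate_calibration_session(u, "test", seed = 44)
    fit <- select_and_finalize(tr, va)
    list(user = u, fit = fit, test_r2 = evaluate_offline(fit, te))
  })
}

fx_baselines_fast <- function() {
  fx_memo("baselines_fast", function() {
    emgdecode:::task_baselines(task_postures(), n_draws = 1e4, seed = 77)
  })
}
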
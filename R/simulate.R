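#' Multi-channel EMG recordings
#'
#' Container for raw surface EMG: a samples x channels numeric matrix plus
#' its sampling rate and channel labels.
#'
#' @param signal Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param channels Optional channel labels (default `ch01`, `ch02`, ...).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs, channels = NULL) {
  signal <- as.matrix(signal)
  stopifnot_scalar_number(fs, "fs", min = 1e-9)
  if (is.null(channels)) {
    channels <- sprintf("ch%02d", seq_len(ncol(signal)))
  }
  colnames(signal) <- channels
  structure(
    list(signal = signal, fs = fs, channels = channels),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  invisible(x)
}

# Resample a DOA trajectory to a target rate by linear interpolation.
resample_doa <- function(traj, fs) {
  y <- doa_matrix(traj)
  t_in <- traj$time
  n_out <- max(2L, round((t_in[length(t_in)] - t_in[1L]) * fs) + 1L)
  t_out <- t_in[1L] + (seq_len(n_out) - 1) / fs
  out <- vapply(seq_len(ncol(y)), function(j) {
    stats::approx(t_in, y[, j], xout = t_out, rule = 2)$y
  }, numeric(n_out))
  list(values = out, times = t_out)
}

#' Simulate raw EMG for a movement intent
#'
#' Generates amplitude-modulated Gaussian EMG: each channel's envelope is the
#' linear synergy mixture of the intent plus the resting baseline, perturbed
#' by multiplicative execution noise (piecewise constant over short segments,
#' SD decaying with block as the virtual user adapts), and the raw signal is
#' the envelope times zero-mean unit-variance white noise.
#'
#' @param intent A [doa_trajectory()] (any rate; internally resampled to
#'   `fs`).
#' @param model A [synergy_model()].
#' @param fs EMG sampling rate in Hz (default 1111, the acquisition rate).
#' @param block Task block index, controls the execution-noise SD.
#' @param seed Optional integer seed; the same seed, inputs and block give a
#'   bit-identical recording. `NULL` draws from the ambient RNG stream.
#' @param noise_segment_s Duration over which one multiplicative execution
#'   noise draw is held constant (default 0.5 s), emulating slow motor noise
#'   rather than per-sample jitter.
#' @return An [emg_recording()].
#' @export
simulate_emg <- function(intent, model, fs = 1111, block = 1, seed = NULL,
                         noise_segment_s = 0.5) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive sampling rate in Hz.")
  }
  rs <- resample_doa(intent, fs)
  with_seed(seed, {
    env <- simulate_envelope(rs$values, model, fs, block, noise_segment_s)
    raw <- env * matrix(rnorm(length(env)), nrow(env), ncol(env))
    emg_recording(raw, fs)
  })
}

# Envelope for an intent matrix (samples x 5) under a synergy model; uses the
# ambient RNG stream for the execution noise.
simulate_envelope <- function(intent_values, model, fs, block,
                              noise_segment_s = 0.5) {
  mix <- mixing_at_block(model, block)
  env <- intent_values %*% t(mix) + model$baseline
  sd_b <- noise_sd_at_block(model, block)
  if (sd_b > 0) {
    n <- nrow(env)
    seg_len <- max(1L, round(noise_segment_s * fs))
    n_seg <- ceiling(n / seg_len)
    seg_of <- rep(seq_len(n_seg), each = seg_len, length.out = n)
    factors <- matrix(1 + rnorm(n_seg * ncol(env), sd = sd_b),
                      n_seg, ncol(env))
    env <- env * pmax(factors[seg_of, , drop = FALSE], 0)
  }
  env
}

#' Generate a full calibration session
#'
#' Emulates one calibration dataset: every motion repetition is a ~7 s
#' movement followed by a 3 s rest, cycling through the nine motions; the
#' training and validation splits contain 10 repetitions per motion and the
#' test split 2. The paired glove stream is obtained by passing the intent
#' through the pseudo-inverse of the glove-to-DOA map plus Gaussian sensor
#' noise, so the linear mapping is exactly recoverable downstream.
#'
#' @param model A [synergy_model()].
#' @param split `"training"`, `"validation"` or `"test"`.
#' @param seed Integer seed; the session is a pure function of
#'   `(model, split, seed, ...)`.
#' @param reps Repetitions per motion; defaults to 10 for training and
#'   validation, 2 for test.
#' @param movement_s,rest_s Segment durations in seconds (defaults 7 and 3).
#' @param fs_emg,fs_glove Sampling rates (defaults 1111 and 25 Hz).
#' @param doa_map Glove-to-DOA map used to synthesize the glove stream
#'   (default [default_doa_map()]).
#' @param glove_noise_sd Glove sensor noise SD as a fraction of range
#'   (default 0.01).
#' @param block Block index forwarded to the execution-noise model.
#' @return A `calibration_session`: list with elements `emg`
#'   ([emg_recording()]), `glove` (list of `signal` matrix at 25 Hz and `fs`),
#'   `labels` (per-EMG-sample movement id, 0 = rest), `intent`
#'   ([doa_trajectory()] at the glove rate), `segments` (tibble of motion
#'   segments), `split`, and `meta`.
#' @export
generate_calibration_session <- function(model, split = c("training",
                                                          "validation",
                                                          "test"),
                                         seed = 1, reps = NULL,
                                         movement_s = 7, rest_s = 3,
                                         fs_emg = 1111, fs_glove = 25,
                                         doa_map = default_doa_map(),
                                         glove_noise_sd = 0.01, block = 1) {
  split <- match.arg(split)
  if (is.null(reps)) {
    reps <- if (split == "test") 2L else 10L
  }
  motions <- calibration_motions()$motion_id
  rest_n <- round(rest_s * fs_glove)
  rest_block <- matrix(0, rest_n, N_DOA)

  pieces <- list(rest_block)
  labels <- list(rep(0L, rest_n))
  seg_rows <- list()
  t_cursor <- rest_s
  for (r in seq_len(reps)) {
    for (m in motions) {
      traj <- make_intent_trajectory(m, duration_s = movement_s,
                                     rate_hz = fs_glove)
      nm <- nrow(traj)
      pieces[[length(pieces) + 1L]] <- doa_matrix(traj)
      labels[[length(labels) + 1L]] <- rep(as.integer(m), nm)
      seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
        motion_id = as.integer(m), rep = r,
        t_start = t_cursor, t_end = t_cursor + nm / fs_glove
      )
      pieces[[length(pieces) + 1L]] <- rest_block
      labels[[length(labels) + 1L]] <- rep(0L, rest_n)
      t_cursor <- t_cursor + nm / fs_glove + rest_s
    }
  }
  intent_values <- do.call(rbind, pieces)
  labels_glove <- unlist(labels)
  times <- (seq_len(nrow(intent_values)) - 1) / fs_glove
  intent <- doa_trajectory(intent_values, times)

  emg <- simulate_emg(intent, model, fs = fs_emg, block = block,
                      seed = seed)
  glove_signal <- with_seed(seed + 1L, {
    glove_from_doa(intent_values, doa_map, noise_sd = glove_noise_sd)
  })
  # Per-EMG-sample labels by nearest glove sample.
  n_emg <- nrow(emg$signal)
  t_emg <- (seq_len(n_emg) - 1) / fs_emg
  idx <- pmin(length(labels_glove), pmax(1L, round(t_emg * fs_glove) + 1L))
  structure(
    list(
      emg = emg,
      glove = list(signal = glove_signal, fs = fs_glove),
      labels = labels_glove[idx],
      intent = intent,
      segments = dplyr::bind_rows(seg_rows),
      split = split,
      meta = list(seed = seed, reps = reps, movement_s = movement_s,
                  rest_s = rest_s, fs_emg = fs_emg, fs_glove = fs_glove,
                  glove_noise_sd = glove_noise_sd, block = block,
                  n_channels = model$n_channels)
    ),
    class = "calibration_session"
  )
}

#' @export
print.calibration_session <- function(x, ...) {
  cat(sprintf(
    "<calibration_session> split = %s; %d motion segments; %.0f s EMG @ %g Hz (%d ch); glove @ %g Hz\n",
    x$split, nrow(x$segments), nrow(x$emg$signal) / x$emg$fs, x$emg$fs,
    ncol(x$emg$signal), x$glove$fs
  ))
  invisible(x)
}

#' One closed-loop correction step of the virtual user
#'
#' Stands in for the participant's compensatory contractions: the next
#' movement intent moves from the current intent toward the target by
#' `gain` times the visually observed error, plus execution noise at the
#' block-dependent SD, clipped to `[0, 1]`.
#'
#' @param intent Current intent, numeric 5-vector in `[0, 1]`.
#' @param target Target posture, numeric 5-vector.
#' @param observed Currently observed (decoded) posture, numeric 5-vector.
#' @param model A [synergy_model()] providing the execution-noise schedule.
#' @param gain Correction gain in `[0, 1]`.
#' @param block Block index (noise schedule).
#' @param seed Optional seed; `NULL` (the default) uses the ambient RNG
#'   stream, as inside [run_virtual_session()].
#' @return The next intent 5-vector.
#' @export
virtual_user_command <- function(intent, target, observed, model, gain,
                                 block = 1, seed = NULL) {
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0 || gain > 1) {
    abort("`gain` must be a single number in [0, 1].")
  }
  with_seed(seed, {
    sd_b <- noise_sd_at_block(model, block)
    noise <- if (sd_b > 0) rnorm(N_DOA, sd = sd_b) else numeric(N_DOA)
    clip01(intent + gain * (target - observed) + noise)
  })
}
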
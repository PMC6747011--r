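#' Sliding-window configuration
#'
#' The EMG stream is processed with a sliding window of 128 ms advanced in
#' 50 ms increments. Windows are right-aligned (the timestamp is the window
#' end, the causal real-time convention) and a trailing partial window is
#' dropped, never padded.
#'
#' @param window_ms Window length in milliseconds (default 128).
#' @param increment_ms Window increment in milliseconds (default 50).
#' @param fs Sampling rate of the signal in Hz.
#' @return An object of class `window_config` with derived
#'   `samples_per_window` and `samples_per_step`.
#' @examples
#' window_config(fs = 1111)
#' @export
window_config <- function(window_ms = 128, increment_ms = 50, fs) {
  stopifnot_scalar_number(window_ms, "window_ms", min = 1e-9)
  stopifnot_scalar_number(increment_ms, "increment_ms", min = 1e-9)
  stopifnot_scalar_number(fs, "fs", min = 1e-9)
  if (window_ms < increment_ms) {
    abort("`window_ms` must be >= `increment_ms`.")
  }
  w <- round(window_ms * fs / 1000)
  s <- round(increment_ms * fs / 1000)
  if (w < 2L) abort("window must span at least 2 samples.")
  if (s < 1L) abort("increment must span at least 1 sample.")
  structure(
    list(window_ms = window_ms, increment_ms = increment_ms, fs = fs,
         samples_per_window = as.integer(w), samples_per_step = as.integer(s)),
    class = "window_config"
  )
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("<window_config> %g/%g ms @ %g Hz (%d samples, step %d)\n",
              x$window_ms, x$increment_ms, x$fs, x$samples_per_window,
              x$samples_per_step))
  invisible(x)
}

# Start indices of all complete windows of an n-sample signal.
window_starts <- function(n, cfg) {
  w <- cfg$samples_per_window
  s <- cfg$samples_per_step
  if (n < w) abort("signal shorter than one window.")
  n_win <- floor((n - w) / s) + 1L
  1L + (seq_len(n_win) - 1L) * s
}

# End-of-window timestamps (seconds) for the grid of an n-sample signal.
window_times <- function(n, cfg) {
  (window_starts(n, cfg) + cfg$samples_per_window - 1L) / cfg$fs
}

#' Cut a single-channel signal into sliding windows
#'
#' @param x Numeric vector (one EMG channel) or an [emg_recording()] (first
#'   channel used).
#' @param cfg A [window_config()].
#' @return Numeric matrix, `samples_per_window` x windows; one column per
#'   window.
#' @export
sliding_windows <- function(x, cfg) {
  if (inherits(x, "emg_recording")) x <- x$signal[, 1L]
  starts <- window_starts(length(x), cfg)
  w <- cfg$samples_per_window
  idx <- outer(seq_len(w) - 1L, starts, `+`)
  matrix(x[idx], nrow = w)
}

#' Time-domain EMG features
#'
#' Per-window scalar features of the time-domain feature bank:
#' * `wilson_amplitude()` — count of consecutive-sample differences
#'   exceeding a threshold in absolute value;
#' * `waveform_length()` — cumulative absolute first difference;
#' * `log_variance()` — natural log of the (population) variance plus `eps`;
#' * `slope_sign_change()` — count of interior turning points with product of
#'   adjacent slopes above a threshold;
#' * `ar_coefficients()` — Yule-Walker AR coefficient estimates via the
#'   Levinson-Durbin recursion (population autocovariance convention);
#'   a zero-variance window yields all-zero coefficients.
#'
#' @param x Numeric vector (one window of one channel).
#' @param threshold Nonnegative threshold; conventional defaults are 10 uV
#'   for Wilson amplitude on volt-scaled recordings and 0 for slope sign
#'   change.
#' @return A scalar count or value; `ar_coefficients()` returns `order`
#'   values.
#' @export
wilson_amplitude <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0) {
    abort("`threshold` must be a single nonnegative number (Inf allowed).")
  }
  sum(abs(diff(x)) > threshold)
}

#' @rdname wilson_amplitude
#' @export
waveform_length <- function(x) {
  sum(abs(diff(x)))
}

#' @rdname wilson_amplitude
#' @param eps Variance floor (default `1e-12`) so constant windows give
#'   `log(eps)` instead of `-Inf`.
#' @export
log_variance <- function(x, eps = 1e-12) {
  stopifnot_scalar_number(eps, "eps", min = 1e-300)
  n <- length(x)
  v <- sum((x - mean(x))^2) / n
  log(v + eps)
}

#' @rdname wilson_amplitude
#' @export
slope_sign_change <- function(x, threshold = 0) {
  stopifnot_scalar_number(threshold, "threshold", min = 0)
  if (length(x) < 3L) abort("slope sign change needs at least 3 samples.")
  mid <- x[2:(length(x) - 1L)]
  sum((mid - x[1:(length(x) - 2L)]) * (mid - x[3:length(x)]) > threshold)
}

#' @rdname wilson_amplitude
#' @param order AR model order (default 4).
#' @export
ar_coefficients <- function(x, order = 4L) {
  n <- length(x)
  if (n <= order) abort("window must be longer than the AR order.")
  xc <- x - mean(x)
  acov <- vapply(0:order, function(j) {
    sum(xc[seq_len(n - j)] * xc[seq_len(n - j) + j]) / n
  }, numeric(1L))
  if (acov[1L] <= 1e-30) return(numeric(order))
  drop(levinson_durbin(matrix(acov, nrow = 1L), order))
}

# Vectorized Levinson-Durbin: `acov` is windows x (order+1) autocovariances
# (lag 0..order); returns windows x order AR coefficients (phi such that
# x_t = sum_k phi_k x_{t-k} + e_t). Rows with zero lag-0 variance come out
# all zero.
levinson_durbin <- function(acov, order = 4L) {
  n <- nrow(acov)
  phi <- matrix(0, n, order)
  err <- acov[, 1L]
  ok <- err > 1e-30
  for (m in seq_len(order)) {
    if (m == 1L) {
      k <- ifelse(ok, acov[, 2L] / err, 0)
    } else {
      accum <- rowSums(phi[, 1:(m - 1L), drop = FALSE] *
                         acov[, m:2, drop = FALSE])
      k <- ifelse(ok & err > 1e-30, (acov[, m + 1L] - accum) / err, 0)
    }
    if (m > 1L) {
      prev <- phi[, 1:(m - 1L), drop = FALSE]
      phi[, 1:(m - 1L)] <- prev - k * prev[, (m - 1L):1, drop = FALSE]
    }
    phi[, m] <- k
    err <- err * (1 - k^2)
  }
  phi[!ok, ] <- 0
  phi
}

# Rolling sums over the window grid. Each window's sum is accumulated
# independently and in sample order (colSums), so a sum computed on a
# full recording is bit-identical to the same sum computed on a single
# extracted window -- the property the streaming decoder relies on.
rolling_window_sum <- function(v, starts, len) {
  idx <- outer(seq_len(len) - 1L, starts, `+`)
  colSums(matrix(v[idx], nrow = len))
}

feature_preset_names <- function(preset = c("paper7", "full8")) {
  preset <- match.arg(preset)
  base <- c("wamp", "ar1", "ar2", "ar3", "ar4", "wl", "logvar")
  if (preset == "full8") base <- c(base, "ssc")
  base
}

#' Extract the time-domain feature matrix from an EMG recording
#'
#' Computes the feature bank for every channel on the sliding-window grid and
#' concatenates channel-major (channel 1's features, then channel 2's, ...).
#' The default preset `"paper7"` uses 7 features per channel (Wilson
#' amplitude, AR1-AR4, waveform length, log-variance); `"full8"` adds slope
#' sign change.
#'
#' @param emg An [emg_recording()] or a samples x channels matrix.
#' @param cfg A [window_config()]; when omitted, the default 128/50 ms
#'   configuration at the recording's sampling rate.
#' @param preset Feature preset, `"paper7"` or `"full8"`.
#' @param wamp_threshold Wilson amplitude threshold (default `1e-5`, i.e.
#'   10 uV on volt-scaled signals; pass a value matched to your units).
#' @param ssc_threshold Slope-sign-change threshold (default 0).
#' @param eps Variance floor for the log-variance feature.
#' @return A `feature_matrix`: list with `values` (windows x
#'   channels*features), `window_times`, `feature_names`, `n_channels`,
#'   `features_per_channel`, and `standardization` (`NULL` until
#'   [standardize_features()]).
#' @export
extract_features <- function(emg, cfg = NULL, preset = c("paper7", "full8"),
                             wamp_threshold = 1e-5, ssc_threshold = 0,
                             eps = 1e-12) {
  preset <- match.arg(preset)
  if (inherits(emg, "emg_recording")) {
    if (is.null(cfg)) cfg <- window_config(fs = emg$fs)
    signal <- emg$signal
  } else {
    if (is.null(cfg)) abort("`cfg` is required for a bare matrix.")
    signal <- as.matrix(emg)
  }
  fnames <- feature_preset_names(preset)
  n <- nrow(signal)
  starts <- window_starts(n, cfg)
  w <- cfg$samples_per_window
  n_win <- length(starts)
  n_ch <- ncol(signal)
  fpc <- length(fnames)
  values <- matrix(NA_real_, n_win, n_ch * fpc)
  for (ch in seq_len(n_ch)) {
    x <- signal[, ch]
    d <- diff(x)
    s1 <- rolling_window_sum(x, starts, w)
    s2 <- rolling_window_sum(x * x, starts, w)
    m1 <- s1 / w
    varw <- pmax(s2 / w - m1^2, 0)
    feats <- list()
    feats$wamp <- rolling_window_sum(abs(d) > wamp_threshold, starts, w - 1L)
    # AR(4) via windowed autocovariances.
    acov <- matrix(0, n_win, 5L)
    acov[, 1L] <- varw
    for (j in 1:4) {
      pj <- x[seq_len(n - j)] * x[seq_len(n - j) + j]
      sp <- rolling_window_sum(pj, starts, w - j)
      # partial sums of x over the two offset sub-ranges of the window
      sa <- rolling_window_sum(x, starts, w - j)
      sb <- rolling_window_sum(x, starts + j, w - j)
      acov[, j + 1L] <- (sp - m1 * (sa + sb) + (w - j) * m1^2) / w
    }
    ar <- levinson_durbin(acov, 4L)
    feats$ar1 <- ar[, 1L]; feats$ar2 <- ar[, 2L]
    feats$ar3 <- ar[, 3L]; feats$ar4 <- ar[, 4L]
    feats$wl <- rolling_window_sum(abs(d), starts, w - 1L)
    feats$logvar <- log(varw + eps)
    if ("ssc" %in% fnames) {
      mid <- x[2:(n - 1L)]
      turn <- (mid - x[1:(n - 2L)]) * (mid - x[3:n]) > ssc_threshold
      feats$ssc <- rolling_window_sum(turn, starts, w - 2L)
    }
    values[, (ch - 1L) * fpc + seq_len(fpc)] <-
      do.call(cbind, feats[fnames])
  }
  ch_labels <- if (!is.null(colnames(signal))) colnames(signal) else
    sprintf("ch%02d", seq_len(n_ch))
  colnames(values) <- as.vector(t(outer(ch_labels, fnames, paste,
                                        sep = "_")))
  structure(
    list(values = values,
         window_times = (starts + w - 1L) / cfg$fs,
         feature_names = colnames(values),
         n_channels = n_ch,
         features_per_channel = fpc,
         preset = preset,
         cfg = cfg,
         wamp_threshold = wamp_threshold,
         ssc_threshold = ssc_threshold,
         standardization = NULL),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d windows x %d columns (%d channels x %d features, preset %s)%s\n",
    nrow(x$values), ncol(x$values), x$n_channels, x$features_per_channel,
    x$preset, if (is.null(x$standardization)) "" else ", standardized"
  ))
  invisible(x)
}

#' EMG envelopes on the processing window grid
#'
#' The envelope is the mean absolute value of the raw signal within each
#' sliding window, per channel, on the same window grid as
#' [extract_features()].
#'
#' @inheritParams extract_features
#' @return Numeric matrix, windows x channels, with a `window_times`
#'   attribute.
#' @export
emg_envelope <- function(emg, cfg = NULL) {
  if (inherits(emg, "emg_recording")) {
    if (is.null(cfg)) cfg <- window_config(fs = emg$fs)
    signal <- emg$signal
  } else {
    if (is.null(cfg)) abort("`cfg` is required for a bare matrix.")
    signal <- as.matrix(emg)
  }
  starts <- window_starts(nrow(signal), cfg)
  w <- cfg$samples_per_window
  out <- vapply(seq_len(ncol(signal)), function(ch) {
    rolling_window_sum(abs(signal[, ch]), starts, w) / w
  }, numeric(length(starts)))
  out <- matrix(out, nrow = length(starts))
  colnames(out) <- colnames(signal)
  attr(out, "window_times") <- (starts + w - 1L) / cfg$fs
  out
}

#' Standardize a feature matrix
#'
#' Columns are standardized by mean subtraction and inverse-SD scaling.
#' Statistics are estimated from the supplied matrix when `stats` is `NULL`
#' (training use) and must be reused for validation/test/streaming data.
#' Zero-variance columns are left centered with unit divisor.
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @param stats Optional list with `mean` and `sd` vectors (training-derived).
#' @return The feature matrix with standardized `values` and the statistics
#'   recorded in `$standardization`.
#' @export
standardize_features <- function(fm, stats = NULL) {
  if (is.null(stats)) {
    mu <- colMeans(fm$values)
    sigma <- apply(fm$values, 2L, sd)
    sigma[!is.finite(sigma) | sigma == 0] <- 1
    stats <- list(mean = mu, sd = sigma)
  }
  fm$values <- sweep(sweep(fm$values, 2L, stats$mean), 2L, stats$sd, `/`)
  fm$standardization <- stats
  fm
}

#' @rdname standardize_features
#' @export
destandardize_features <- function(fm) {
  if (is.null(fm$standardization)) abort("feature matrix is not standardized.")
  st <- fm$standardization
  fm$values <- sweep(sweep(fm$values, 2L, st$sd, `*`), 2L, st$mean, `+`)
  fm$standardization <- NULL
  fm
}
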
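#' Build the lag-stacked design matrix
#'
#' Row `n` of the lagged design concatenates the feature vectors of windows
#' `n, n-1, ..., n-M+1` (lag 0 first). The first `M - 1` rows are zero-padded
#' for missing lags so real-time prediction is defined from the first window,
#' and a constant-1 bias column is appended last. With the default feature
#' preset, 16 channels and `M = 6` this yields 672 lagged columns plus bias.
#'
#' @param features A standardized `feature_matrix` or a windows x features
#'   numeric matrix.
#' @param M Number of time lags (default 6, i.e. a 300 ms filter at 50 ms
#'   increments).
#' @return Numeric matrix, windows x (features*M + 1), with attributes
#'   `bias_col` (index of the bias column) and `M`.
#' @export
build_lagged_design <- function(features, M = 6L) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (M < 1L) abort("`M` must be >= 1.")
  if (M > nrow(X)) abort("`M` exceeds the number of windows.")
  n <- nrow(X)
  p <- ncol(X)
  out <- matrix(0, n, p * M + 1L)
  for (lag in 0:(M - 1L)) {
    rows <- (lag + 1L):n
    out[rows, lag * p + seq_len(p)] <- X[rows - lag, , drop = FALSE]
  }
  out[, p * M + 1L] <- 1
  structure(out, bias_col = p * M + 1L, M = M)
}

# Column indices of a sensor subset inside a lagged design built from a
# channel-major feature matrix (plus the bias column).
lagged_sensor_columns <- function(sensors, features_per_channel, n_channels,
                                  M, bias = TRUE) {
  sensors <- as.integer(sensors)
  features_per_channel <- as.integer(features_per_channel)
  n_channels <- as.integer(n_channels)
  M <- as.integer(M)
  base <- as.vector(vapply(sort(sensors), function(ch) {
    (ch - 1L) * features_per_channel + seq_len(features_per_channel)
  }, integer(features_per_channel)))
  p <- n_channels * features_per_channel
  cols <- as.vector(vapply(0:(M - 1L), function(lag) lag * p + base,
                           integer(length(base))))
  if (bias) cols <- c(cols, p * M + 1L)
  cols
}

# Ridge-regularized Wiener solve from correlation matrices: (Rxx + lambda*P)
# H = Rxy with P the identity zeroed at the bias row, via Cholesky.
solve_wiener_gram <- function(Rxx, Rxy, lambda, bias_col) {
  A <- Rxx
  pen <- rep(lambda, ncol(A))
  if (!is.null(bias_col)) pen[bias_col] <- 0
  diag(A) <- diag(A) + pen
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    abort("normal equations are singular; use a regularization lambda > 0.")
  }
  backsolve(ch, forwardsolve(t(ch), Rxy))
}

#' Fit the regularized Wiener filter
#'
#' Solves the L2-regularized least-squares problem through auto- and
#' cross-correlation matrices: `(R_xx + lambda I) H = R_xy` with
#' `R_xx = X'X / N` and `R_xy = X'Y / N`. The bias column is excluded from
#' the penalty, and the system is solved by a symmetric positive-definite
#' (Cholesky) factorization, never an explicit inverse.
#'
#' @param X Lagged design matrix (from [build_lagged_design()]).
#' @param Y Target matrix, windows x 5 (normalized DOA positions).
#' @param lambda Regularization strength, `>= 0`.
#' @param bias_col Index of the unpenalized bias column; defaults to the
#'   design's `bias_col` attribute (or none when absent).
#' @return Weight matrix `H`, columns(X) x columns(Y).
#' @export
fit_wiener <- function(X, Y, lambda, bias_col = attr(X, "bias_col")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have the same number of rows.")
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    abort("non-finite values in the inputs.")
  }
  stopifnot_scalar_number(lambda, "lambda", min = 0)
  n <- nrow(X)
  solve_wiener_gram(crossprod(X) / n, crossprod(X, Y) / n, lambda, bias_col)
}

#' Exponential smoothing of decoder output
#'
#' Applies the first-order recursion
#' `y_smooth[n] = alpha * y[n] + (1 - alpha) * y_smooth[n-1]` per DOA, with
#' `y_smooth[1] = y[1]`. `alpha = 1` is the identity; smaller `alpha` smooths
#' more at the cost of response latency.
#'
#' @param y Numeric vector or windows x K matrix of raw predictions.
#' @param alpha Smoothing parameter in `[0, 1]`.
#' @return Smoothed trajectory of the same shape.
#' @export
exp_smooth <- function(y, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1].")
  }
  vec <- is.null(dim(y))
  y <- as.matrix(y)
  if (alpha == 1) return(if (vec) drop(y) else y)
  out <- apply(y, 2L, function(col) {
    if (length(col) == 1L) return(col)
    smoothed <- stats::filter(alpha * col[-1L], 1 - alpha,
                              method = "recursive", init = col[1L])
    c(col[1L], as.numeric(smoothed))
  })
  out <- matrix(out, nrow = nrow(y), dimnames = dimnames(y))
  if (vec) drop(out) else out
}

#' Multivariate R-squared
#'
#' The pooled coefficient of determination across all K output dimensions:
#' one minus the ratio of the total squared error to the total squared
#' deviation of the observations from their per-output means. Pooled, not
#' averaged per output; may be negative for predictions worse than the mean.
#'
#' @param y_true,y_pred Matrices of the same shape (samples x K).
#' @return A single number, at most 1.
#' @export
multivariate_r2 <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    abort("`y_true` and `y_pred` must have the same shape.")
  }
  denom <- sum(sweep(y_true, 2L, colMeans(y_true))^2)
  if (denom <= 0) {
    abort("`y_true` is constant in every output; R^2 is undefined.")
  }
  1 - sum((y_true - y_pred)^2) / denom
}

#' Construct a trained decoder object
#'
#' Bundles everything needed to run the decoder causally on new EMG: filter
#' weights, lag count, selected sensors, regularization and smoothing
#' parameters, the training-derived feature standardization statistics, the
#' DOA normalization ranges, and the windowing/feature configuration.
#' Usually produced by [select_and_finalize()] or [train_wiener_model()],
#' not called directly.
#'
#' @param weights Weight matrix for the sensor-subset lagged design
#'   (+ bias row last).
#' @param sensors Integer vector of selected channel indices.
#' @param lambda,alpha Chosen regularization and smoothing parameters.
#' @param M Lag count.
#' @param feat_stats Standardization list (`mean`, `sd`) for the subset
#'   feature columns, in subset order.
#' @param ranges DOA normalization tibble from [doa_ranges()].
#' @param cfg [window_config()] used for feature extraction.
#' @param preset,wamp_threshold,ssc_threshold Feature-bank settings.
#' @param n_channels Total channel count of the recordings the model expects.
#' @param trace Optional [model selection][select_and_finalize()] trace.
#' @return An object of class `wiener_model`.
#' @export
wiener_model <- function(weights, sensors, lambda, alpha, M, feat_stats,
                         ranges, cfg, preset = "paper7",
                         wamp_threshold = 1e-5, ssc_threshold = 0,
                         n_channels = length(sensors), trace = NULL) {
  if (!all(is.finite(weights))) abort("non-finite weights.")
  structure(
    list(weights = weights, sensors = sort(as.integer(sensors)),
         lambda = lambda, alpha = alpha, M = as.integer(M),
         feat_stats = feat_stats, ranges = ranges, cfg = cfg,
         preset = preset, wamp_threshold = wamp_threshold,
         ssc_threshold = ssc_threshold, n_channels = as.integer(n_channels),
         trace = trace),
    class = "wiener_model"
  )
}

#' @export
print.wiener_model <- function(x, ...) {
  cat(sprintf(
    "<wiener_model> %d sensors, M = %d lags, lambda = %g, alpha = %.2f; %d weights x %d DOAs\n",
    length(x$sensors), x$M, x$lambda, x$alpha, nrow(x$weights),
    ncol(x$weights)
  ))
  invisible(x)
}

# Features (standardized, subset order) for the model's sensor subset from a
# raw EMG recording or signal matrix.
model_features <- function(model, emg) {
  signal <- if (inherits(emg, "emg_recording")) emg$signal else as.matrix(emg)
  if (ncol(signal) < max(model$sensors)) {
    abort(sprintf(
      "recording has %d channels but the model's sensor set needs channel %d.",
      ncol(signal), max(model$sensors)
    ))
  }
  fm <- extract_features(signal[, model$sensors, drop = FALSE],
                         cfg = model$cfg, preset = model$preset,
                         wamp_threshold = model$wamp_threshold,
                         ssc_threshold = model$ssc_threshold)
  standardize_features(fm, model$feat_stats)
}

#' Decode finger positions from EMG
#'
#' Runs the full causal inference path: feature extraction on the model's
#' sensor subset, standardization with the training statistics, lag stacking,
#' the linear filter, exponential smoothing, and clipping to `[0, 1]`
#' (physical actuator limits).
#'
#' @param object A `wiener_model`.
#' @param emg An [emg_recording()] or samples x channels matrix covering all
#'   channels the model was trained on.
#' @param smooth Apply exponential smoothing (default `TRUE`); raw unsmoothed
#'   (and unclipped) predictions are returned when `FALSE`.
#' @param ... Unused.
#' @return A [doa_trajectory()] on the feature window grid.
#' @export
predict.wiener_model <- function(object, emg, smooth = TRUE, ...) {
  fm <- model_features(object, emg)
  X <- build_lagged_design(fm, object$M)
  # Row-by-row product so that batch and streaming prediction share the
  # same accumulation order and agree bit-for-bit (a blocked full-matrix
  # multiply can differ in the last ulp).
  raw <- matrix(NA_real_, nrow(X), ncol(object$weights))
  for (i in seq_len(nrow(X))) {
    raw[i, ] <- X[i, , drop = FALSE] %*% object$weights
  }
  times <- fm$window_times
  if (!smooth) return(doa_trajectory(raw, times))
  doa_trajectory(clip01(exp_smooth(raw, object$alpha)), times)
}
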
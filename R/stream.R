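# Streaming (real-time) decoding: feed raw samples in chunks, get one
# prediction per completed window. Arithmetic is kept identical to the batch
# path (same per-window accumulation order, same standardization, smoothing
# and clipping expressions), so streaming and batch predictions on the same
# stream agree bit-for-bit.

# Feature vector for a single window (samples x channels), vectorized across
# channels. Mirrors extract_features() arithmetic exactly: every per-window
# quantity is a colSums over the same samples in the same order.
single_window_features <- function(win, fnames, wamp_threshold,
                                   ssc_threshold, eps = 1e-12) {
  w <- nrow(win)
  d <- diff(win)
  s1 <- colSums(win)
  s2 <- colSums(win * win)
  m1 <- s1 / w
  varw <- pmax(s2 / w - m1^2, 0)
  feats <- list()
  feats$wamp <- colSums(abs(d) > wamp_threshold)
  acov <- matrix(0, ncol(win), 5L)
  acov[, 1L] <- varw
  for (j in 1:4) {
    sp <- colSums(win[seq_len(w - j), , drop = FALSE] *
                    win[seq_len(w - j) + j, , drop = FALSE])
    sa <- colSums(win[seq_len(w - j), , drop = FALSE])
    sb <- colSums(win[seq_len(w - j) + j, , drop = FALSE])
    acov[, j + 1L] <- (sp - m1 * (sa + sb) + (w - j) * m1^2) / w
  }
  ar <- levinson_durbin(acov, 4L)
  feats$ar1 <- ar[, 1L]; feats$ar2 <- ar[, 2L]
  feats$ar3 <- ar[, 3L]; feats$ar4 <- ar[, 4L]
  feats$wl <- colSums(abs(d))
  feats$logvar <- log(varw + eps)
  if ("ssc" %in% fnames) {
    mid <- win[2:(w - 1L), , drop = FALSE]
    feats$ssc <- colSums((mid - win[1:(w - 2L), , drop = FALSE]) *
                           (mid - win[3:w, , drop = FALSE]) > ssc_threshold)
  }
  # channel-major: channel 1's features first
  as.vector(t(do.call(cbind, feats[fnames])))
}

#' Streaming decoder state
#'
#' [decoder_stream_init()] creates the mutable state for causal, real-time
#' use of a trained decoder; [decoder_stream_feed()] appends raw EMG samples
#' and emits one smoothed, clipped DOA prediction per completed 128 ms
#' window on the 50 ms grid. Feeding a recording chunk by chunk reproduces
#' [predict.wiener_model()] on the same recording exactly.
#'
#' @param model A `wiener_model`.
#' @return An environment holding the raw-sample buffer, the feature lag
#'   buffer (zero-initialized, matching the batch zero-padding of early
#'   lags) and the smoothing state.
#' @export
decoder_stream_init <- function(model) {
  p <- length(model$sensors) * n_preset_features(model$preset)
  state <- new.env(parent = emptyenv())
  state$buffer <- matrix(numeric(0), 0L, length(model$sensors))
  state$lagvec <- numeric(p * model$M)
  state$p <- p
  state$smooth <- NULL
  state
}

n_preset_features <- function(preset) length(feature_preset_names(preset))

#' @rdname decoder_stream_init
#' @param state State from [decoder_stream_init()].
#' @param samples New raw samples, a matrix with one column per channel of
#'   the full montage (the model's sensor subset is extracted internally).
#' @return `decoder_stream_feed()`: matrix of 0 or more rows x 5 DOA
#'   predictions (one row per completed window); the state is updated in
#'   place.
#' @export
decoder_stream_feed <- function(model, state, samples) {
  samples <- if (is.null(dim(samples))) matrix(samples, nrow = 1L) else
    as.matrix(samples)
  if (ncol(samples) >= model$n_channels) {
    samples <- samples[, model$sensors, drop = FALSE]
  } else if (ncol(samples) != length(model$sensors)) {
    abort("sample columns match neither the full montage nor the sensor subset.")
  }
  state$buffer <- rbind(state$buffer, samples)
  w <- model$cfg$samples_per_window
  s <- model$cfg$samples_per_step
  fnames <- feature_preset_names(model$preset)
  out <- list()
  while (nrow(state$buffer) >= w) {
    win <- state$buffer[seq_len(w), , drop = FALSE]
    f <- single_window_features(win, fnames, model$wamp_threshold,
                                model$ssc_threshold)
    f <- (f - model$feat_stats$mean) / model$feat_stats$sd
    state$lagvec <- c(f, state$lagvec[seq_len(state$p * (model$M - 1L))])
    y <- as.numeric(matrix(c(state$lagvec, 1), 1L) %*% model$weights)
    if (is.null(state$smooth)) {
      state$smooth <- y
    } else {
      state$smooth <- model$alpha * y + (1 - model$alpha) * state$smooth
    }
    out[[length(out) + 1L]] <- clip01(state$smooth)
    state$buffer <- state$buffer[-seq_len(s), , drop = FALSE]
  }
  if (length(out) == 0L) {
    return(matrix(numeric(0), 0L, N_DOA, dimnames = list(NULL, DOA_NAMES)))
  }
  m <- do.call(rbind, out)
  colnames(m) <- DOA_NAMES
  m
}
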
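#' Glove-to-DOA linear map
#'
#' Converts 18-DOF data-glove streams to the five normalized prosthesis
#' degrees of actuation (DOAs) through an affine map `weights %*% g +
#' offsets`. The experiment used a calibrated linear mapping whose matrix is
#' not reproduced here; [default_doa_map()] ships a documented synthetic
#' default that groups flexion sensors per digit (thumb rotation from the
#' thumb-abduction sensor, ring and little fingers pooled into their shared
#' DOA, sensors 16-18 unused), and any user-supplied `5 x 18` matrix is
#' accepted.
#'
#' @param weights Numeric `5 x 18` matrix.
#' @param offsets Numeric 5-vector added after the matrix product
#'   (default zeros).
#' @return An object of class `doa_map`.
#' @export
doa_map <- function(weights, offsets = rep(0, N_DOA)) {
  weights <- as.matrix(weights)
  if (nrow(weights) != N_DOA) {
    abort(sprintf("`weights` must have %d rows (one per DOA).", N_DOA))
  }
  if (any(rowSums(abs(weights)) == 0)) {
    abort("every DOA row of `weights` needs at least one nonzero entry.")
  }
  rownames(weights) <- DOA_NAMES
  structure(
    list(weights = weights, offsets = as.numeric(offsets),
         n_glove = ncol(weights)),
    class = "doa_map"
  )
}

#' @rdname doa_map
#' @param n_glove Number of glove sensors (default 18).
#' @export
default_doa_map <- function(n_glove = 18) {
  w <- matrix(0, N_DOA, n_glove)
  groups <- list(
    thumb_rotation = 1L,      # thumb abduction sensor
    thumb_flexion  = 2:3,     # thumb MCP + IP
    index          = 4:6,
    middle         = 7:9,
    ring_little    = 10:15    # ring and little pooled (coupled DOA)
  )
  for (j in seq_along(groups)) {
    idx <- groups[[j]]
    w[j, idx] <- 1 / length(idx)
  }
  doa_map(w)
}

#' @export
print.doa_map <- function(x, ...) {
  cat(sprintf("<doa_map> %d DOAs x %d glove sensors\n", nrow(x$weights),
              x$n_glove))
  invisible(x)
}

# Synthesize a glove stream realizing a DOA intent: pseudo-inverse of the
# map plus Gaussian sensor noise (ambient RNG stream).
glove_from_doa <- function(doa_values, map, noise_sd = 0.01) {
  pinv <- MASS::ginv(map$weights)
  g <- sweep(doa_values, 2L, map$offsets) %*% t(pinv)
  if (noise_sd > 0) {
    g <- g + matrix(rnorm(length(g), sd = noise_sd), nrow(g), ncol(g))
  }
  g
}

#' Average glove samples onto the EMG processing window grid
#'
#' Computes the mean glove value per DOF within each 128 ms window on the
#' 50 ms grid (right-aligned, matching [extract_features()]). Windows that
#' contain no glove sample inherit the previous window's value.
#'
#' @param glove Either the `glove` element of a calibration session (list
#'   with `signal` and `fs`) or a samples x DOF matrix.
#' @param cfg A [window_config()] (its `fs` is the EMG rate defining the
#'   shared time grid).
#' @param fs_glove Glove sampling rate in Hz, required when `glove` is a bare
#'   matrix.
#' @param n_windows Optional number of windows; defaults to the count implied
#'   by the glove duration, pass the EMG window count to share one grid.
#' @return Numeric matrix, windows x DOFs, with a `window_times` attribute
#'   (window end times in seconds).
#' @export
window_average_glove <- function(glove, cfg, fs_glove = NULL,
                                 n_windows = NULL) {
  if (is.list(glove) && !is.null(glove$signal)) {
    fs_glove <- glove$fs
    glove <- glove$signal
  }
  glove <- as.matrix(glove)
  if (nrow(glove) == 0L) abort("glove stream is empty.")
  if (is.null(fs_glove)) abort("`fs_glove` is required for a bare matrix.")
  # The shared grid is defined by the EMG *sample* counts (window of
  # round(128 ms * fs) samples advanced by round(50 ms * fs) samples), so
  # window end times are taken from the sample grid; using the nominal
  # millisecond values would drift from the EMG grid over a long session.
  w_s <- cfg$samples_per_window / cfg$fs
  s_s <- cfg$samples_per_step / cfg$fs
  duration <- nrow(glove) / fs_glove
  if (is.null(n_windows)) {
    n_windows <- floor((duration - w_s) / s_s) + 1L
    if (n_windows < 1L) abort("glove stream shorter than one window.")
  }
  ends <- w_s + (seq_len(n_windows) - 1) * s_s
  t_glove <- (seq_len(nrow(glove)) - 1) / fs_glove
  # Window k covers (ends[k] - w_s, ends[k]]; assign samples to windows.
  out <- matrix(NA_real_, n_windows, ncol(glove))
  hi <- findInterval(ends + 1e-9, t_glove)
  lo <- findInterval(ends - w_s + 1e-9, t_glove) + 1L
  for (k in seq_len(n_windows)) {
    if (hi[k] >= lo[k]) {
      out[k, ] <- colMeans(glove[lo[k]:hi[k], , drop = FALSE])
    } else if (k > 1L) {
      out[k, ] <- out[k - 1L, ]
    } else {
      out[k, ] <- glove[max(1L, hi[k]), ]
    }
  }
  attr(out, "window_times") <- ends
  out
}

#' Apply a glove-to-DOA map to windowed glove data
#'
#' @param glove_windows Windows x 18 matrix (from [window_average_glove()]).
#' @param map A [doa_map()].
#' @return Unnormalized DOA matrix, windows x 5, preserving the
#'   `window_times` attribute.
#' @export
glove_to_doa <- function(glove_windows, map) {
  glove_windows <- as.matrix(glove_windows)
  if (ncol(glove_windows) != map$n_glove) {
    abort(sprintf("expected %d glove columns, got %d.", map$n_glove,
                  ncol(glove_windows)))
  }
  out <- glove_windows %*% t(map$weights)
  out <- sweep(out, 2L, map$offsets, `+`)
  colnames(out) <- DOA_NAMES
  attr(out, "window_times") <- attr(glove_windows, "window_times")
  out
}

#' Per-DOA normalization ranges from training data
#'
#' @param doa Unnormalized DOA matrix (training split only).
#' @return Tibble with `doa`, `min`, `max` per DOA.
#' @export
doa_ranges <- function(doa) {
  doa <- as.matrix(doa)
  mins <- apply(doa, 2L, min)
  maxs <- apply(doa, 2L, max)
  tibble::tibble(doa = DOA_NAMES, min = mins, max = maxs)
}

#' Normalize DOA trajectories to [0, 1]
#'
#' Affine rescaling `(y - min) / (max - min)` with per-DOA ranges estimated
#' on the training split only; values outside the training range are clipped
#' to `[0, 1]` (0 = full extension, 1 = full flexion).
#'
#' @param doa Windows x 5 unnormalized DOA matrix.
#' @param ranges Tibble from [doa_ranges()] computed on training data.
#' @return Windows x 5 matrix in `[0, 1]`.
#' @export
normalize_doa <- function(doa, ranges) {
  doa <- as.matrix(doa)
  degenerate <- ranges$max - ranges$min <= 0
  if (any(degenerate)) {
    abort(sprintf("degenerate normalization range (min == max) for DOA: %s",
                  paste(ranges$doa[degenerate], collapse = ", ")))
  }
  out <- sweep(doa, 2L, ranges$min)
  out <- sweep(out, 2L, ranges$max - ranges$min, `/`)
  out <- clip01(out)
  colnames(out) <- DOA_NAMES
  attr(out, "window_times") <- attr(doa, "window_times")
  out
}
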
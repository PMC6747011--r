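#' Virtual user: synergy model of the neuromuscular system
#'
#' The synthetic-session generator stands in for a participant's neuromuscular
#' system with a linear synergy model: each EMG channel's envelope is a
#' nonnegative mixture of the five movement intents plus a resting baseline.
#' Two per-block mechanisms emulate short-term user adaptation:
#'
#' * execution noise with standard deviation
#'   `noise_sd0 * exp(-adaptation_rate * (block - 1))`, so practice reduces
#'   motor variability across the six task blocks;
#' * a slow rotation of the mixing-matrix columns in channel space by
#'   `rotation_rate * (block - 1)` radians, so the covariance structure of the
#'   EMG envelopes (the muscle co-activation pattern) drifts with practice.
#'
#' @param n_channels Number of EMG channels (16 by default; the amputee
#'   presets use 13 and 12).
#' @param mixing Optional `n_channels x 5` nonnegative mixing matrix. When
#'   `NULL` a seeded random matrix is drawn in which each DOA drives three
#'   primary channels strongly and all channels weakly.
#' @param noise_sd0 Initial execution-noise SD (envelope units, relative),
#'   `> 0` unless a noiseless user is wanted.
#' @param adaptation_rate Per-block exponential decay rate of the execution
#'   noise (`>= 0`; 0 disables adaptation).
#' @param rotation_rate Per-block rotation angle (radians, `>= 0`) of the
#'   mixing columns; 0 freezes the co-activation structure.
#' @param baseline Resting envelope level (arbitrary amplitude units) so rest
#'   is nonzero, as in real recordings.
#' @param seed Integer seed controlling the random mixing matrix and the
#'   rotation plane.
#' @return An object of class `synergy_model`.
#' @examples
#' user <- synergy_model(seed = 1)
#' noise_sd_at_block(user, 1:6)
#' @export
synergy_model <- function(n_channels = 16, mixing = NULL, noise_sd0 = 0.1,
                          adaptation_rate = 0.3, rotation_rate = 0,
                          baseline = 0.02, seed = 1) {
  stopifnot_scalar_number(noise_sd0, "noise_sd0", min = 0)
  stopifnot_scalar_number(adaptation_rate, "adaptation_rate", min = 0)
  stopifnot_scalar_number(rotation_rate, "rotation_rate", min = 0)
  stopifnot_scalar_number(baseline, "baseline", min = 0)
  if (is.null(mixing)) {
    mixing <- with_seed(seed, {
      m <- matrix(runif(n_channels * N_DOA, 0, 0.25), n_channels, N_DOA)
      for (j in seq_len(N_DOA)) {
        primary <- sample(n_channels, min(3L, n_channels))
        m[primary, j] <- m[primary, j] + runif(length(primary), 0.7, 1.2)
      }
      m
    })
  }
  mixing <- as.matrix(mixing)
  if (any(mixing < 0)) abort("`mixing` must be nonnegative.")
  if (ncol(mixing) != N_DOA) {
    abort(sprintf("`mixing` must have %d columns.", N_DOA))
  }
  if (qr(mixing)$rank < N_DOA) {
    abort("`mixing` must have full column rank (rank 5).")
  }
  # Fixed orthonormal pair spanning the rotation plane in channel space.
  plane <- with_seed(seed + 1L, {
    q <- qr.Q(qr(matrix(rnorm(nrow(mixing) * 2L), ncol = 2L)))
    q
  })
  structure(
    list(
      mixing = mixing,
      n_channels = nrow(mixing),
      noise_sd0 = noise_sd0,
      adaptation_rate = adaptation_rate,
      rotation_rate = rotation_rate,
      baseline = baseline,
      rotation_plane = plane,
      seed = seed
    ),
    class = "synergy_model"
  )
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf(
    "<synergy_model> %d channels x %d DOAs; noise_sd0 = %g, adaptation_rate = %g, rotation_rate = %g rad/block\n",
    x$n_channels, ncol(x$mixing), x$noise_sd0, x$adaptation_rate,
    x$rotation_rate
  ))
  invisible(x)
}

#' Amputee emulation presets
#'
#' Convenience constructors for the reduced electrode counts used with the
#' two amputee participants (13 and 12 channels).
#'
#' @inheritParams synergy_model
#' @param preset `"able_bodied"` (16 channels), `"amputee1"` (13) or
#'   `"amputee2"` (12).
#' @param ... Passed on to [synergy_model()].
#' @return A `synergy_model`.
#' @export
synergy_model_preset <- function(preset = c("able_bodied", "amputee1",
                                            "amputee2"), ...) {
  preset <- match.arg(preset)
  n <- switch(preset, able_bodied = 16L, amputee1 = 13L, amputee2 = 12L)
  synergy_model(n_channels = n, ...)
}

#' Execution-noise SD at a given block
#'
#' @param model A [synergy_model()].
#' @param block Block index (1-based); may be a vector.
#' @return `noise_sd0 * exp(-adaptation_rate * (block - 1))`.
#' @export
noise_sd_at_block <- function(model, block) {
  model$noise_sd0 * exp(-model$adaptation_rate * (block - 1))
}

#' Mixing matrix at a given block
#'
#' Applies the per-block rotation of the mixing columns in the model's fixed
#' channel-space plane.
#'
#' @param model A [synergy_model()].
#' @param block Block index (1-based).
#' @return The rotated `n_channels x 5` mixing matrix.
#' @export
mixing_at_block <- function(model, block) {
  theta <- model$rotation_rate * (block - 1)
  if (theta == 0) return(model$mixing)
  u <- model$rotation_plane[, 1L]
  v <- model$rotation_plane[, 2L]
  rot <- diag(model$n_channels) +
    (cos(theta) - 1) * (tcrossprod(u) + tcrossprod(v)) +
    sin(theta) * (tcrossprod(v, u) - tcrossprod(u, v))
  rot %*% model$mixing
}
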
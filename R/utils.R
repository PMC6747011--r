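# Internal helpers shared across modules.

# Names of the five degrees of actuation of the prosthetic hand, in the
# column order used throughout the package. The ring and little fingers are
# mechanically coupled and share one DOA.
DOA_NAMES <- c("thumb_rotation", "thumb_flexion", "index", "middle",
               "ring_little")

N_DOA <- 5L

# Clip values into [lo, hi] without dropping dimensions.
clip01 <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. With seed = NULL the expression uses the
# ambient RNG stream (needed inside larger seeded simulations).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Minimum-jerk position profile on tau in [0, 1].
min_jerk <- function(tau) {
  tau <- clip01(tau)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, min))
  }
  invisible(x)
}
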
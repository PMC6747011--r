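#' Principal-component analysis of EMG envelopes for one block
#'
#' Covariance PCA of the channel-space envelope data (channels share units,
#' so no correlation scaling), with a deterministic sign convention: each
#' component's largest-magnitude loading is made positive.
#'
#' @param envelopes Windows x channels envelope matrix (from
#'   [emg_envelope()] or a session log's `block_envelopes`).
#' @param n_components Components to retain (default all channels).
#' @return A `block_pca`: list with `rotation` (channels x k, orthonormal
#'   columns), `ev_ratio` (explained-variance ratios, descending) and
#'   `n_channels`.
#' @export
block_pca <- function(envelopes, n_components = NULL) {
  envelopes <- as.matrix(envelopes)
  if (all(apply(envelopes, 2L, function(v) var(v) == 0))) {
    abort("envelope data has zero variance in every channel.")
  }
  k <- if (is.null(n_components)) ncol(envelopes) else
    min(n_components, ncol(envelopes))
  pc <- prcomp(envelopes, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pc$sdev^2
  structure(
    list(rotation = rot, ev_ratio = (ev / sum(ev))[seq_len(k)],
         n_channels = ncol(envelopes)),
    class = "block_pca"
  )
}

#' @export
print.block_pca <- function(x, ...) {
  cat(sprintf("<block_pca> %d channels, %d components; PC1 explains %.1f%%\n",
              x$n_channels, ncol(x$rotation), 100 * x$ev_ratio[1L]))
  invisible(x)
}

#' Absolute cosine similarity between two vectors
#'
#' `|a . b| / (|a| |b|)`; the absolute value is used because the sign of a
#' principal-component direction is arbitrary.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
abs_cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity of a zero vector.")
  abs(sum(a * b)) / (na * nb)
}

#' Match principal components between two blocks
#'
#' Greedy matching in descending reference-variance order: reference PC 1
#' claims the other block's PC with the highest absolute cosine similarity,
#' then PC 2 claims the best among the unclaimed components, and so on.
#'
#' @param reference,other `block_pca` objects with the same channel count.
#' @param k Number of components to match.
#' @return Tibble with `ref_pc`, `matched_pc`, `similarity`.
#' @export
match_components <- function(reference, other, k = 2L) {
  k <- min(k, ncol(reference$rotation), ncol(other$rotation))
  unclaimed <- seq_len(ncol(other$rotation))
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sims <- vapply(unclaimed, function(j) {
      abs_cosine_similarity(reference$rotation[, i], other$rotation[, j])
    }, numeric(1L))
    pick <- which.max(sims)
    out[[i]] <- tibble::tibble(ref_pc = i, matched_pc = unclaimed[pick],
                               similarity = sims[pick])
    unclaimed <- unclaimed[-pick]
  }
  dplyr::bind_rows(out)
}

#' Variance explained in one block by another block's components
#'
#' Projects the (centered) block data onto the top-k reference components
#' and reports the projected variance as a percentage of the block's total
#' variance. By projection optimality this can never exceed the variance
#' explained by the block's own top-k components.
#'
#' @param envelopes Windows x channels envelope data of the block to score.
#' @param reference `block_pca` whose components are used (e.g. block 1's).
#' @param k Number of components.
#' @return Percentage in `[0, 100]`.
#' @export
variance_explained_by_reference <- function(envelopes, reference, k = 2L) {
  envelopes <- as.matrix(envelopes)
  if (ncol(envelopes) != reference$n_channels) {
    abort("channel dimension differs between data and reference PCA.")
  }
  k <- min(k, ncol(reference$rotation))
  centered <- sweep(envelopes, 2L, colMeans(envelopes))
  proj <- centered %*% reference$rotation[, seq_len(k), drop = FALSE]
  100 * sum(colSums(proj^2)) / sum(centered^2)
}

#' Mean raw EMG power per block for sensor groups
#'
#' Power is the mean squared raw sample per channel (no detrending); the
#' group value is the mean over the group's channels. Accepts either a
#' `session_log` (uses its accumulated per-block channel power and the
#' decoder's sensor set) or a tibble with `block`, `channel`, `power`.
#'
#' @param x A `session_log` or a per-block per-channel power tibble.
#' @param used,non_used Disjoint channel index vectors; for a session log
#'   they default to the decoder's selected sensors and the rest.
#' @return Tibble with `block`, `group` (`"used"`/`"non_used"`), `power`.
#' @export
channel_power_by_block <- function(x, used = NULL, non_used = NULL) {
  if (inherits(x, "session_log")) {
    if (is.null(x$block_power)) {
      abort("session log has no EMG power record (glove mode?).")
    }
    if (is.null(used)) used <- x$sensors
    if (is.null(non_used)) non_used <- setdiff(seq_len(x$n_channels), used)
    x <- x$block_power
  }
  if (length(intersect(used, non_used)) > 0L) {
    abort("`used` and `non_used` must be disjoint.")
  }
  groups <- list(used = used, non_used = non_used)
  out <- list()
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0L) {
      warn(sprintf("empty sensor group '%s' omitted.", g))
      next
    }
    sub <- x[x$channel %in% groups[[g]], ]
    out[[g]] <- dplyr::summarise(dplyr::group_by(sub, .data$block),
                                 power = mean(.data$power),
                                 .groups = "drop")
    out[[g]]$group <- g
  }
  dplyr::bind_rows(out)[, c("block", "group", "power")]
}

#' Output variability during the evaluation phase
#'
#' Per trial, the standard deviation (population convention) of each DOA
#' across the evaluation-phase samples, averaged over the five DOAs.
#'
#' @param x A `session_log` or a list of evaluation-phase trajectories
#'   (samples x 5 matrices).
#' @return Tibble with one row per trial: `block` (when available), `trial`,
#'   `sd`.
#' @export
doa_variability <- function(x) {
  if (inherits(x, "session_log")) {
    trajs <- x$trials$eval_traj
    meta <- x$trials[, c("block", "trial")]
  } else {
    trajs <- x
    meta <- tibble::tibble(block = NA_integer_, trial = seq_along(trajs))
  }
  sds <- vapply(trajs, function(tr) {
    tr <- as.matrix(tr)
    if (nrow(tr) == 0L) abort("empty evaluation phase.")
    if (nrow(tr) == 1L) {
      warn("single-sample evaluation phase; SD is 0.")
      return(0)
    }
    mean(apply(tr, 2L, function(v) sqrt(mean((v - mean(v))^2))))
  }, numeric(1L))
  dplyr::bind_cols(meta, tibble::tibble(sd = sds))
}

#' Block-wise adaptation report for a session
#'
#' Computes, per block, the absolute cosine similarity of the first two
#' principal components of the EMG envelopes against block 1 (after greedy
#' matching), the percentage of variance explained by block 1's PC1 and
#' PC1+PC2, and the same percentages for each block's own components.
#'
#' @param log An EMG-mode `session_log` (or a list of per-block envelope
#'   matrices).
#' @param k Components tracked (default 2).
#' @return An `adaptation_report` tibble with one row per block.
#' @export
analyze_adaptation <- function(log, k = 2L) {
  env_blocks <- if (inherits(log, "session_log")) log$block_envelopes else log
  if (is.null(env_blocks)) abort("no per-block envelopes available.")
  pcas <- lapply(env_blocks, block_pca)
  ref <- pcas[[1L]]
  out <- dplyr::bind_rows(lapply(seq_along(env_blocks), function(b) {
    m <- match_components(ref, pcas[[b]], k = k)
    tibble::tibble(
      block = b,
      sim_pc1 = m$similarity[1L],
      sim_pc2 = if (k >= 2L) m$similarity[2L] else NA_real_,
      var_ref_pc1 = variance_explained_by_reference(env_blocks[[b]], ref, 1L),
      var_ref_pc12 = variance_explained_by_reference(env_blocks[[b]], ref,
                                                     min(2L, k)),
      var_own_pc1 = 100 * pcas[[b]]$ev_ratio[1L],
      var_own_pc12 = 100 * sum(pcas[[b]]$ev_ratio[seq_len(min(2L, k))])
    )
  }))
  class(out) <- c("adaptation_report", class(out))
  out
}
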
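#' Tidy a trained Wiener decoder
#'
#' Returns one row per filter weight: the feature term, its time lag, the
#' output DOA and the estimate. The bias row is labelled `"(bias)"` with lag
#' `NA`.
#'
#' @param x A `wiener_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `channel`, `feature`, `lag`, `doa`,
#'   `estimate`.
#' @exportS3Method generics::tidy
tidy.wiener_model <- function(x, ...) {
  fpc <- n_preset_features(x$preset)
  fnames <- feature_preset_names(x$preset)
  sensors <- x$sensors
  p <- length(sensors) * fpc
  n_rows <- nrow(x$weights)
  lag <- c(rep(0:(x$M - 1L), each = p), NA_integer_)
  channel <- c(rep(rep(sensors, each = fpc), x$M), NA_integer_)
  feature <- c(rep(rep(fnames, times = length(sensors)), x$M), "(bias)")
  term <- ifelse(is.na(lag), "(bias)",
                 sprintf("ch%02d_%s_lag%d", channel, feature, lag))
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble::tibble(term = term, channel = channel, feature = feature,
                     lag = lag),
      tibble::as_tibble(as.data.frame(x$weights)) |>
        rlang::set_names(DOA_NAMES)
    ),
    cols = dplyr::all_of(DOA_NAMES), names_to = "doa",
    values_to = "estimate"
  )
  stopifnot(nrow(out) == n_rows * N_DOA)
  out
}

#' Glance at a trained Wiener decoder
#'
#' @param x A `wiener_model`.
#' @param ... Unused.
#' @return One-row tibble with the selected sensor count, lambda, alpha, lag
#'   count, input dimensionality and (when a selection trace is present) the
#'   best validation multivariate R-squared.
#' @exportS3Method generics::glance
glance.wiener_model <- function(x, ...) {
  best_r2 <- NA_real_
  if (!is.null(x$trace) && nrow(x$trace$evaluations) > 0L) {
    acc <- x$trace$evaluations[x$trace$evaluations$accepted, ]
    if (nrow(acc) > 0L) best_r2 <- max(acc$r2)
  }
  tibble::tibble(
    n_sensors = length(x$sensors),
    lambda = x$lambda,
    alpha = x$alpha,
    lags = x$M,
    d_lagged = nrow(x$weights) - 1L,
    validation_r2 = best_r2
  )
}

#' Tidy a session log
#'
#' @param x A `session_log`.
#' @param ... Unused.
#' @return The per-trial tibble without the trajectory list column.
#' @exportS3Method generics::tidy
tidy.session_log <- function(x, ...) {
  dplyr::select(x$trials, -"eval_traj")
}

#' Glance at a session log
#'
#' @param x A `session_log`.
#' @param ... Unused.
#' @return One-row tibble with trial counts and summary MAE/score.
#' @exportS3Method generics::glance
glance.session_log <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_trials = nrow(x$trials),
    n_blocks = max(x$trials$block),
    median_mae = median(x$trials$mae),
    median_score = median(x$trials$score)
  )
}
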
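#' Prepare aligned decoding data from a calibration session
#'
#' Extracts the (unstandardized) EMG feature matrix and the normalized DOA
#' target matrix on one shared window grid.
#'
#' @param session A `calibration_session`.
#' @param cfg Optional [window_config()] (default 128/50 ms at the session's
#'   EMG rate).
#' @param map [doa_map()] used to convert the glove stream (default
#'   [default_doa_map()]).
#' @param ranges DOA normalization ranges from the *training* split
#'   ([doa_ranges()]); when `NULL` they are estimated from this session,
#'   which is only appropriate for the training split itself.
#' @param preset,wamp_threshold,ssc_threshold Feature-bank settings, see
#'   [extract_features()].
#' @return List with `features` (a `feature_matrix`), `targets` (windows x 5
#'   matrix in `[0, 1]`), and `ranges`.
#' @export
prepare_decoding_data <- function(session, cfg = NULL,
                                  map = default_doa_map(), ranges = NULL,
                                  preset = "paper7", wamp_threshold = 1e-5,
                                  ssc_threshold = 0) {
  if (is.null(cfg)) cfg <- window_config(fs = session$emg$fs)
  fm <- extract_features(session$emg, cfg, preset = preset,
                         wamp_threshold = wamp_threshold,
                         ssc_threshold = ssc_threshold)
  n_win <- nrow(fm$values)
  glove_w <- window_average_glove(session$glove, cfg, n_windows = n_win)
  raw <- glove_to_doa(glove_w, map)
  if (is.null(ranges)) ranges <- doa_ranges(raw)
  targets <- normalize_doa(raw, ranges)
  list(features = fm, targets = targets, ranges = ranges)
}

# Fit a sensor subset from precomputed Gram matrices and score it on the
# validation design. Returns list(r2, weights, cols).
eval_sensor_subset <- function(gram, sensors, lambda) {
  cols <- lagged_sensor_columns(sensors, gram$fpc, gram$n_channels, gram$M)
  H <- solve_wiener_gram(gram$G[cols, cols, drop = FALSE],
                         gram$C[cols, , drop = FALSE],
                         lambda, bias_col = length(cols))
  pred <- gram$X_valid[, cols, drop = FALSE] %*% H
  list(r2 = multivariate_r2(gram$Y_valid, pred), weights = H, cols = cols,
       pred = pred)
}

# Precompute the training Gram matrices and validation design shared by the
# selection stages. `features_*` must already be standardized with the
# training statistics.
selection_gram <- function(features_train, targets_train, features_valid,
                           targets_valid, M) {
  X_tr <- build_lagged_design(features_train$values, M)
  X_va <- build_lagged_design(features_valid$values, M)
  n <- nrow(X_tr)
  list(G = crossprod(X_tr) / n, C = crossprod(X_tr, targets_train) / n,
       X_train = X_tr, Y_train = targets_train,
       X_valid = X_va, Y_valid = targets_valid,
       fpc = features_train$features_per_channel,
       n_channels = features_train$n_channels, M = M)
}

#' Sequential forward sensor selection
#'
#' Greedy electrode-subset search: starting from the empty set, each
#' iteration adds the channel whose inclusion maximizes validation-set
#' multivariate R-squared (ties broken by lowest channel index), and the
#' search stops when the best remaining addition strictly decreases the
#' current best score. Fits during this stage use a fixed provisional
#' regularization `lambda` (default `1e-3`, the midpoint of the later search
#' grid), recorded in the trace.
#'
#' @param features_train,features_valid Standardized `feature_matrix`
#'   objects (training statistics applied to both).
#' @param targets_train,targets_valid Normalized DOA target matrices.
#' @param M Lag count (default 6).
#' @param lambda Provisional regularization used for the stage's fits.
#' @return List with `sensors` (ordered as selected), `r2` (best validation
#'   score) and `trace` (one row per candidate evaluation).
#' @export
sequential_forward_sensors <- function(features_train, targets_train,
                                       features_valid, targets_valid,
                                       M = 6L, lambda = 1e-3) {
  gram <- selection_gram(features_train, targets_train, features_valid,
                         targets_valid, M)
  sfs_stage(gram, lambda)
}

sfs_stage <- function(gram, lambda) {
  n_ch <- gram$n_channels
  selected <- integer(0)
  best_r2 <- -Inf
  trace <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(seq_len(n_ch), selected)
    if (length(remaining) == 0L) break
    step <- step + 1L
    scores <- vapply(remaining, function(ch) {
      eval_sensor_subset(gram, c(selected, ch), lambda)$r2
    }, numeric(1L))
    best_i <- which.max(scores)   # first max = lowest channel index on ties
    accepted <- scores[best_i] >= best_r2
    trace[[step]] <- tibble::tibble(
      stage = "sensors", step = step, candidate = remaining,
      value = NA_real_, n_sensors = length(selected) + 1L, r2 = scores,
      accepted = accepted & remaining == remaining[best_i]
    )
    if (!accepted) break
    selected <- c(selected, remaining[best_i])
    best_r2 <- scores[best_i]
  }
  if (length(selected) == 0L) {  # single noisy channel still gets returned
    selected <- 1L
    best_r2 <- eval_sensor_subset(gram, selected, lambda)$r2
  }
  list(sensors = selected, r2 = best_r2,
       trace = dplyr::bind_rows(trace), lambda_provisional = lambda)
}

#' Regularization grid search
#'
#' Evaluates the eight-point logarithmic grid `10^-6, 10^-5, ..., 10^1` for
#' the ridge parameter of the Wiener filter on the validation set, with the
#' sensor subset fixed from the previous stage. Ties go to the smaller
#' lambda.
#'
#' @inheritParams sequential_forward_sensors
#' @param sensors Fixed sensor subset.
#' @param lambdas Candidate grid (default `10^(-6:1)`).
#' @return List with `lambda`, `r2`, and `trace`.
#' @export
grid_search_lambda <- function(features_train, targets_train, features_valid,
                               targets_valid, sensors, M = 6L,
                               lambdas = 10^(-6:1)) {
  gram <- selection_gram(features_train, targets_train, features_valid,
                         targets_valid, M)
  lambda_stage(gram, sensors, lambdas)
}

lambda_stage <- function(gram, sensors, lambdas = 10^(-6:1)) {
  fits <- lapply(lambdas, function(l) eval_sensor_subset(gram, sensors, l))
  scores <- vapply(fits, `[[`, numeric(1L), "r2")
  best <- which.max(scores)  # first max = smallest lambda on ties
  list(lambda = lambdas[best], r2 = scores[best],
       raw_valid_pred = fits[[best]]$pred,
       trace = tibble::tibble(stage = "lambda", step = seq_along(lambdas),
                              candidate = NA_integer_, value = lambdas,
                              n_sensors = length(sensors), r2 = scores,
                              accepted = seq_along(lambdas) == best))
}

#' Smoothing-parameter line search
#'
#' Evaluates the exponential-smoothing parameter on the grid
#' `0.00, 0.01, ..., 1.00` (101 values) by smoothing the precomputed raw
#' validation predictions — smoothing is a post-process, so no refitting is
#' needed — and scoring multivariate R-squared against the validation
#' targets (after clipping to `[0, 1]`, as at deployment). Ties go to the
#' larger alpha (less response latency).
#'
#' @param raw_valid_pred Raw (unsmoothed) validation predictions.
#' @param targets_valid Validation target matrix.
#' @param alphas Candidate grid (default `seq(0, 1, by = 0.01)`).
#' @return List with `alpha`, `r2`, and `trace`.
#' @export
line_search_alpha <- function(raw_valid_pred, targets_valid,
                              alphas = seq(0, 1, by = 0.01)) {
  scores <- vapply(alphas, function(a) {
    multivariate_r2(targets_valid, clip01(exp_smooth(raw_valid_pred, a)))
  }, numeric(1L))
  best_score <- max(scores)
  best <- max(which(scores == best_score))  # larger alpha on exact ties
  list(alpha = alphas[best], r2 = best_score,
       trace = tibble::tibble(stage = "alpha", step = seq_along(alphas),
                              candidate = NA_integer_, value = alphas,
                              n_sensors = NA_integer_, r2 = scores,
                              accepted = seq_along(alphas) == best))
}

#' Three-stage model selection and final training
#'
#' Runs the full calibration procedure: (1) sequential forward sensor
#' selection, (2) ridge-parameter grid search, (3) smoothing-parameter line
#' search — in that order, each maximizing validation-set multivariate
#' R-squared — then merges the training and validation sets and refits the
#' final filter with the chosen sensors and lambda. Feature standardization
#' statistics and DOA normalization ranges are estimated from the training
#' split only; the test split is never touched here.
#'
#' @param train,valid `calibration_session` objects for the training and
#'   validation splits.
#' @param cfg Optional [window_config()].
#' @param map [doa_map()] for the glove stream.
#' @param M Lag count (default 6; a 300 ms filter at 50 ms increments).
#' @param sensors Optional fixed sensor subset; skips stage 1 (fixed-montage
#'   use).
#' @param lambda,alpha Optional fixed values; skip the corresponding stage.
#' @param preset,wamp_threshold,ssc_threshold Feature-bank settings.
#' @param sfs_lambda Provisional lambda for the sensor-selection fits.
#' @return A [wiener_model()] whose `$trace` holds the full selection trace
#'   (a tibble of every candidate evaluation) plus the chosen values.
#' @examples
#' \donttest{
#' user <- synergy_model(noise_sd0 = 0, seed = 2)
#' tr <- generate_calibration_session(user, "training", seed = 10,
#'                                    reps = 2, movement_s = 3, rest_s = 1)
#' va <- generate_calibration_session(user, "validation", seed = 11,
#'                                    reps = 2, movement_s = 3, rest_s = 1)
#' fit <- select_and_finalize(tr, va, sensors = 1:16)
#' glance(fit)
#' }
#' @export
select_and_finalize <- function(train, valid, cfg = NULL,
                                map = default_doa_map(), M = 6L,
                                sensors = NULL, lambda = NULL, alpha = NULL,
                                preset = "paper7", wamp_threshold = 1e-5,
                                ssc_threshold = 0, sfs_lambda = 1e-3) {
  if (is.null(cfg)) cfg <- window_config(fs = train$emg$fs)
  tr <- prepare_decoding_data(train, cfg, map, ranges = NULL, preset = preset,
                              wamp_threshold = wamp_threshold,
                              ssc_threshold = ssc_threshold)
  va <- prepare_decoding_data(valid, cfg, map, ranges = tr$ranges,
                              preset = preset,
                              wamp_threshold = wamp_threshold,
                              ssc_threshold = ssc_threshold)
  fm_tr <- standardize_features(tr$features)
  stats <- fm_tr$standardization
  fm_va <- standardize_features(va$features, stats)
  gram <- selection_gram(fm_tr, tr$targets, fm_va, va$targets, M)

  traces <- list()
  if (is.null(sensors)) {
    stage1 <- sfs_stage(gram, sfs_lambda)
    sensors <- stage1$sensors
    traces$sensors <- stage1$trace
  }
  if (is.null(lambda)) {
    stage2 <- lambda_stage(gram, sensors)
    lambda <- stage2$lambda
    raw_valid <- stage2$raw_valid_pred
    traces$lambda <- stage2$trace
  } else {
    raw_valid <- eval_sensor_subset(gram, sensors, lambda)$pred
  }
  if (is.null(alpha)) {
    stage3 <- line_search_alpha(raw_valid, va$targets)
    alpha <- stage3$alpha
    traces$alpha <- stage3$trace
  }

  # Merge training and validation sets and refit with the chosen values.
  cols <- lagged_sensor_columns(sensors, gram$fpc, gram$n_channels, gram$M)
  X_all <- rbind(gram$X_train[, cols, drop = FALSE],
                 gram$X_valid[, cols, drop = FALSE])
  Y_all <- rbind(gram$Y_train, gram$Y_valid)
  n_all <- nrow(X_all)
  H <- solve_wiener_gram(crossprod(X_all) / n_all,
                         crossprod(X_all, Y_all) / n_all,
                         lambda, bias_col = length(cols))

  sorted <- sort(sensors)
  base_cols <- as.vector(vapply(sorted, function(ch) {
    (ch - 1L) * gram$fpc + seq_len(gram$fpc)
  }, integer(gram$fpc)))
  feat_stats <- list(mean = stats$mean[base_cols], sd = stats$sd[base_cols])

  trace <- dplyr::bind_rows(traces)
  wiener_model(
    weights = H, sensors = sensors, lambda = lambda, alpha = alpha, M = M,
    feat_stats = feat_stats, ranges = tr$ranges, cfg = cfg, preset = preset,
    wamp_threshold = wamp_threshold, ssc_threshold = ssc_threshold,
    n_channels = gram$n_channels,
    trace = list(evaluations = trace,
                 chosen = list(sensors = sort(as.integer(sensors)),
                               lambda = lambda, alpha = alpha),
                 stage_order = names(traces))
  )
}

#' Offline reconstruction accuracy of a trained decoder
#'
#' Scores the full inference pipeline (features, filter, smoothing,
#' clipping) against a held-out session's normalized glove targets with the
#' multivariate R-squared.
#'
#' @param model A `wiener_model`.
#' @param session A `calibration_session` (typically the test split).
#' @param map [doa_map()] used for the session's glove stream.
#' @return A single number (multivariate R-squared).
#' @export
evaluate_offline <- function(model, session, map = default_doa_map()) {
  dat <- prepare_decoding_data(session, model$cfg, map,
                               ranges = model$ranges, preset = model$preset,
                               wamp_threshold = model$wamp_threshold,
                               ssc_threshold = model$ssc_threshold)
  pred <- predict(model, session$emg)
  multivariate_r2(dat$targets, doa_matrix(pred))
}
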
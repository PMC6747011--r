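#' The 18 task postures
#'
#' Nine hand shapes, each at half and full activation, give the 18 target
#' postures of the posture-matching task.
#'
#' @param shapes Template table (default [task_shapes()]).
#' @return Tibble with `posture_id`, `shape`, `activation` and the five
#'   target DOA columns.
#' @export
task_postures <- function(shapes = task_shapes()) {
  out <- tidyr::expand_grid(shape = shapes$shape,
                            activation = c("half", "full"))
  targets <- t(vapply(seq_len(nrow(out)), function(i) {
    tpl <- as.numeric(shapes[shapes$shape == out$shape[i], DOA_NAMES])
    half_full_target(tpl, out$activation[i])
  }, numeric(N_DOA)))
  colnames(targets) <- DOA_NAMES
  dplyr::bind_cols(tibble::tibble(posture_id = seq_len(nrow(out))), out,
                   tibble::as_tibble(as.data.frame(targets)))
}

#' Half or full activation of a shape template
#'
#' Full activation is the template itself; half activation halves every DOA.
#'
#' @param template Numeric 5-vector in `[0, 1]`.
#' @param activation `"half"` or `"full"`.
#' @return Target posture 5-vector.
#' @export
half_full_target <- function(template, activation = c("full", "half")) {
  activation <- match.arg(activation)
  template <- as.numeric(template)
  if (any(template < 0 | template > 1)) {
    abort("`template` values must lie in [0, 1].")
  }
  if (activation == "half") template / 2 else template
}

#' Build the posture-matching task protocol
#'
#' Six blocks; within each block all 18 postures appear exactly once in a
#' seeded pseudo-random order, so the stimulus sequence is reproducible and
#' can be shared across virtual subjects.
#'
#' @param seed Integer seed for the per-block permutations.
#' @param blocks Number of blocks (default 6).
#' @param postures Posture table from [task_postures()].
#' @param drive_s,eval_s Drive and evaluation phase durations in seconds
#'   (defaults 3.5 and 1.5).
#' @param update_ms Position update interval (default 50 ms, the window
#'   increment).
#' @param rest_after_block Rest between blocks in seconds (protocol
#'   metadata).
#' @return A `task_protocol`: tibble with one row per trial (`block`,
#'   `trial`, `posture_id`) and the timing as attributes.
#' @export
build_protocol <- function(seed = 1, blocks = 6L, postures = task_postures(),
                           drive_s = 3.5, eval_s = 1.5, update_ms = 50,
                           rest_after_block = 3) {
  n_post <- nrow(postures)
  order <- with_seed(seed, {
    lapply(seq_len(blocks), function(b) sample(postures$posture_id))
  })
  out <- dplyr::bind_rows(lapply(seq_len(blocks), function(b) {
    tibble::tibble(block = b, trial = seq_len(n_post),
                   posture_id = order[[b]])
  }))
  structure(out, class = c("task_protocol", class(out)),
            postures = postures, drive_s = drive_s, eval_s = eval_s,
            update_ms = update_ms, rest_after_block = rest_after_block,
            seed = seed)
}

#' Trial mean absolute error
#'
#' Per evaluation sample, the MAE between target and performed posture is
#' the mean over the five DOAs of the absolute position error; the trial
#' value is the median across the evaluation-phase samples.
#'
#' @param target Numeric 5-vector in `[0, 1]`.
#' @param performed Evaluation-phase trajectory, samples x 5 matrix (a
#'   single 5-vector is accepted).
#' @return A single nonnegative number.
#' @export
trial_mae <- function(target, performed) {
  if (is.null(dim(performed))) performed <- matrix(performed, nrow = 1L)
  performed <- as.matrix(performed)
  if (nrow(performed) == 0L) abort("empty evaluation phase.")
  if (ncol(performed) != length(target)) {
    abort("`performed` must have one column per DOA of `target`.")
  }
  median(rowMeans(abs(sweep(performed, 2L, as.numeric(target)))))
}

#' Monte-Carlo random-prediction baseline MAE
#'
#' The median MAE between a target posture and uniform random postures in
#' `[0, 1]^5`, estimated from `n_draws` simulated random predictions. The
#' seed is fixed so the same baselines are shared across virtual subjects.
#'
#' @param target Numeric 5-vector in `[0, 1]`.
#' @param n_draws Number of random predictions (default `1e6`).
#' @param seed Integer seed.
#' @return The baseline median MAE.
#' @export
random_baseline_mae <- function(target, n_draws = 1e6, seed = 20190910) {
  target <- as.numeric(target)
  if (any(target < 0 | target > 1)) abort("`target` must lie in [0, 1].")
  with_seed(seed, {
    draws <- matrix(runif(n_draws * length(target)), n_draws)
    median(rowMeans(abs(sweep(draws, 2L, target))))
  })
}

# Baseline MAE for every posture of a protocol (shared across subjects).
task_baselines <- function(postures, n_draws = 1e6, seed = 20190910) {
  vapply(seq_len(nrow(postures)), function(i) {
    random_baseline_mae(as.numeric(postures[i, DOA_NAMES]), n_draws,
                        seed = seed + postures$posture_id[i])
  }, numeric(1L))
}

#' Normalized trial score
#'
#' Rescales a trial MAE against the posture's random baseline:
#' `max(0, 1 - mae / baseline) * 100`, so perfect reproduction scores 100%
#' and random performance about 0%; negative values are floored at 0.
#'
#' @param mae Trial MAE.
#' @param baseline Baseline MAE from [random_baseline_mae()], `> 0`.
#' @return Score in percent.
#' @export
normalized_score <- function(mae, baseline) {
  if (any(baseline <= 0)) abort("`baseline` must be positive.")
  pmax(0, 1 - mae / baseline) * 100
}

#' Run a virtual closed-loop posture-matching session
#'
#' Simulates the real-time experiment with a virtual user: each trial resets
#' the hand to fully open and the decoder state, then runs a 3.5 s drive
#' phase in closed loop (user correction toward the target, EMG synthesis,
#' windowed features, Wiener prediction, smoothing) followed by a 1.5 s
#' evaluation phase during which the intent is frozen (plus execution noise)
#' and the performed trajectory is scored. In `glove` mode the decoder is
#' bypassed and the hand follows the glove stream (intent through the
#' pseudo-inverse map plus sensor noise) — the task's performance benchmark.
#'
#' @param model A `wiener_model` (required for `mode = "emg"`).
#' @param user A [synergy_model()] virtual user.
#' @param protocol A [build_protocol()] table.
#' @param mode `"emg"` or `"glove"`.
#' @param seed Integer seed for all within-session randomness.
#' @param gain Virtual-user correction gain in `[0, 1]`.
#' @param map [doa_map()] used in glove mode.
#' @param glove_noise_sd Glove sensor noise SD (glove mode).
#' @param baselines Optional per-posture baseline MAEs (computed once and
#'   reused across sessions); default recomputes with
#'   [random_baseline_mae()] at `n_baseline_draws`.
#' @param n_baseline_draws Draws for the random baseline (default `1e6`).
#' @param baseline_seed Seed of the shared random baseline.
#' @return A `session_log`: `trials` tibble (block, trial, posture, MAE,
#'   score, evaluation trajectory as a list column), per-block envelope
#'   matrices and channel power (EMG mode), and the run's parameters.
#' @export
run_virtual_session <- function(model = NULL, user, protocol = NULL,
                                mode = c("emg", "glove"), seed = 1,
                                gain = 0.7, map = default_doa_map(),
                                glove_noise_sd = 0.01, baselines = NULL,
                                n_baseline_draws = 1e6,
                                baseline_seed = 20190910) {
  mode <- match.arg(mode)
  if (mode == "emg" && is.null(model)) abort("`model` is required in EMG mode.")
  if (is.null(protocol)) protocol <- build_protocol(seed)
  postures <- attr(protocol, "postures")
  drive_steps <- round(attr(protocol, "drive_s") * 1000 /
                         attr(protocol, "update_ms"))
  eval_steps <- round(attr(protocol, "eval_s") * 1000 /
                        attr(protocol, "update_ms"))
  if (is.null(baselines)) {
    baselines <- task_baselines(postures, n_baseline_draws, baseline_seed)
  }
  target_mat <- as.matrix(postures[, DOA_NAMES])
  pinv_w <- MASS::ginv(map$weights)

  n_blocks <- max(protocol$block)
  env_blocks <- vector("list", n_blocks)
  pow_sum <- matrix(0, n_blocks, user$n_channels)
  pow_n <- numeric(n_blocks)

  with_seed(seed, {
    rows <- vector("list", nrow(protocol))
    for (i in seq_len(nrow(protocol))) {
      b <- protocol$block[i]
      pid <- protocol$posture_id[i]
      target <- target_mat[pid, ]
      res <- run_trial(model, user, target, b, mode, gain, drive_steps,
                       eval_steps, map, pinv_w, glove_noise_sd)
      if (mode == "emg") {
        env_blocks[[b]] <- rbind(env_blocks[[b]], res$envelopes)
        pow_sum[b, ] <- pow_sum[b, ] + res$power_sum
        pow_n[b] <- pow_n[b] + res$power_n
      }
      mae <- trial_mae(target, res$eval_traj)
      rows[[i]] <- tibble::tibble(
        mode = mode, block = b, trial = protocol$trial[i], posture_id = pid,
        shape = postures$shape[pid], activation = postures$activation[pid],
        mae = mae, score = normalized_score(mae, baselines[pid]),
        eval_traj = list(res$eval_traj)
      )
    }
    trials <- dplyr::bind_rows(rows)
    block_power <- NULL
    if (mode == "emg") {
      block_power <- dplyr::bind_rows(lapply(seq_len(n_blocks), function(b) {
        tibble::tibble(block = b, channel = seq_len(user$n_channels),
                       power = pow_sum[b, ] / pow_n[b])
      }))
    }
    structure(
      list(trials = trials,
           block_envelopes = if (mode == "emg") env_blocks else NULL,
           block_power = block_power,
           protocol = protocol, mode = mode, seed = seed, gain = gain,
           sensors = if (!is.null(model)) model$sensors else NULL,
           n_channels = user$n_channels,
           baselines = baselines),
      class = "session_log"
    )
  })
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %s control: %d trials in %d blocks; median MAE %.3f, median score %.1f%%\n",
    x$mode, nrow(x$trials), max(x$trials$block), median(x$trials$mae),
    median(x$trials$score)
  ))
  invisible(x)
}

# One closed-loop trial. Returns the evaluation trajectory plus per-trial
# EMG summaries (EMG mode). Uses the ambient RNG stream.
run_trial <- function(model, user, target, block, mode, gain, drive_steps,
                      eval_steps, map, pinv_w, glove_noise_sd) {
  intent <- numeric(N_DOA)
  observed <- numeric(N_DOA)  # hand reset to fully open
  if (mode == "glove") {
    traj <- matrix(NA_real_, drive_steps + eval_steps, N_DOA)
    frozen <- intent
    for (k in seq_len(drive_steps + eval_steps)) {
      if (k <= drive_steps) {
        intent <- virtual_user_command(intent, target, observed, user, gain,
                                       block)
      } else {
        sd_b <- noise_sd_at_block(user, block)
        jitter <- if (sd_b > 0) rnorm(N_DOA, sd = sd_b) else numeric(N_DOA)
        intent <- clip01(frozen + jitter)
      }
      if (k == drive_steps) frozen <- intent
      g <- pinv_w %*% intent
      if (glove_noise_sd > 0) g <- g + rnorm(length(g), sd = glove_noise_sd)
      observed <- clip01(drop(map$weights %*% g) + map$offsets)
      traj[k, ] <- observed
    }
    return(list(eval_traj = traj[drive_steps + seq_len(eval_steps), ,
                                 drop = FALSE]))
  }

  state <- decoder_stream_init(model)
  w <- model$cfg$samples_per_window
  s <- model$cfg$samples_per_step
  fs <- model$cfg$fs
  mix <- mixing_at_block(user, block)
  sd_b <- noise_sd_at_block(user, block)
  n_steps <- drive_steps + eval_steps
  traj <- matrix(NA_real_, n_steps, N_DOA)
  envelopes <- matrix(NA_real_, n_steps, user$n_channels)
  power_sum <- numeric(user$n_channels)
  power_n <- 0

  emg_chunk <- function(intent, n_samples) {
    env <- drop(mix %*% intent) + user$baseline
    if (sd_b > 0) env <- pmax(env * (1 + rnorm(length(env), sd = sd_b)), 0)
    raw <- matrix(rnorm(n_samples * length(env)), n_samples) *
      rep(env, each = n_samples)
    raw
  }

  # Pre-roll at rest so the first update step completes the first window;
  # `full_win` keeps the trailing 128 ms of *all* channels for the envelope
  # record (the PCA analysis uses every electrode, not just the decoded set).
  pre <- emg_chunk(numeric(N_DOA), w - s)
  power_sum <- power_sum + colSums(pre^2); power_n <- power_n + nrow(pre)
  decoder_stream_feed(model, state, pre)
  full_win <- pre
  frozen <- intent
  for (k in seq_len(n_steps)) {
    if (k <= drive_steps) {
      intent <- virtual_user_command(intent, target, observed, user, gain,
                                     block)
      if (k == drive_steps) frozen <- intent
    } else {
      jitter <- if (sd_b > 0) rnorm(N_DOA, sd = sd_b) else numeric(N_DOA)
      intent <- clip01(frozen + jitter)
    }
    chunk <- emg_chunk(intent, s)
    power_sum <- power_sum + colSums(chunk^2); power_n <- power_n + nrow(chunk)
    pred <- decoder_stream_feed(model, state, chunk)
    observed <- pred[nrow(pred), ]
    traj[k, ] <- observed
    full_win <- rbind(full_win, chunk)
    if (nrow(full_win) > w) {
      full_win <- full_win[nrow(full_win) - w + seq_len(w), , drop = FALSE]
    }
    envelopes[k, ] <- colMeans(abs(full_win))
  }
  list(eval_traj = traj[drive_steps + seq_len(eval_steps), , drop = FALSE],
       envelopes = envelopes,
       power_sum = power_sum, power_n = power_n)
}
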
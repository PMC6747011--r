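#' DOA trajectories
#'
#' A DOA trajectory is a tibble time series of the five normalized digit
#' positions (degrees of actuation) of the prosthetic hand, each in `[0, 1]`
#' (0 = full extension, 1 = full flexion), with a `time` column in seconds.
#'
#' @param values Numeric matrix (samples x 5) of DOA positions.
#' @param times Numeric vector of sample times in seconds.
#' @return A `doa_trajectory` tibble with columns `time`, `thumb_rotation`,
#'   `thumb_flexion`, `index`, `middle`, `ring_little`.
#' @export
doa_trajectory <- function(values, times) {
  values <- as.matrix(values)
  if (ncol(values) != N_DOA) {
    abort(sprintf("`values` must have %d columns (one per DOA).", N_DOA))
  }
  if (length(times) != nrow(values)) {
    abort("`times` must have one entry per row of `values`.")
  }
  colnames(values) <- DOA_NAMES
  out <- tibble::as_tibble(as.data.frame(values))
  out <- tibble::add_column(out, time = as.numeric(times), .before = 1L)
  class(out) <- c("doa_trajectory", class(out))
  out
}

#' Extract the samples x 5 DOA matrix from a trajectory
#'
#' @param traj A [doa_trajectory()].
#' @return Numeric matrix with the five DOA columns.
#' @export
doa_matrix <- function(traj) {
  as.matrix(traj[, DOA_NAMES, drop = FALSE])
}

#' Intended movement trajectory for a calibration motion
#'
#' Builds the movement intent for one repetition of a calibration motion: a
#' minimum-jerk ramp from the rest pose (all DOAs at 0) up to the motion's
#' template posture, a hold, and a minimum-jerk ramp back to rest. The first
#' and last samples are exactly the rest pose.
#'
#' @param motion_id Integer 1-9, indexing [calibration_motions()].
#' @param duration_s Movement duration in seconds (default 7, the duration of
#'   one motion execution in the calibration protocol).
#' @param rate_hz Sampling rate of the returned trajectory (default 25, the
#'   data-glove rate).
#' @param ramp_s Rise/fall time of the minimum-jerk ramps in seconds.
#' @return A [doa_trajectory()] with `round(duration_s * rate_hz)` samples.
#' @examples
#' traj <- make_intent_trajectory(3, duration_s = 7, rate_hz = 25)
#' range(traj$index)
#' @export
make_intent_trajectory <- function(motion_id, duration_s = 7, rate_hz = 25,
                                   ramp_s = 1.5) {
  stopifnot_scalar_number(duration_s, "duration_s", min = 1e-9)
  stopifnot_scalar_number(rate_hz, "rate_hz", min = 1e-9)
  template <- motion_template(motion_id)
  n <- max(2L, round(duration_s * rate_hz))
  times <- (seq_len(n) - 1) / rate_hz
  span <- times[n]
  ramp <- min(ramp_s, span / 2)
  profile <- numeric(n)
  profile[times < ramp] <- min_jerk(times[times < ramp] / ramp)
  profile[times >= ramp & times <= span - ramp] <- 1
  tail_idx <- times > span - ramp
  profile[tail_idx] <- min_jerk((span - times[tail_idx]) / ramp)
  doa_trajectory(outer(profile, template), times)
}
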
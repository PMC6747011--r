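#' Posture templates for calibration motions and task postures
#'
#' The calibration protocol uses nine motions ranging from individuated-finger
#' to full-hand movements; the posture-matching task uses nine hand shapes,
#' each presented at half and full activation. Templates give, for each shape,
#' the target position of the five degrees of actuation (DOAs) of the
#' prosthetic hand on the normalized scale where 0 is full extension and 1
#' full flexion. The source experiment names the shapes but not their joint
#' values, so these templates are a synthetic, editable stand-in: any tibble
#' with columns `shape`, `thumb_rotation`, `thumb_flexion`, `index`, `middle`,
#' `ring_little` can be passed wherever a template table is accepted.
#'
#' @return A tibble with one row per shape and the five DOA columns.
#' @examples
#' calibration_motions()
#' task_shapes()
#' @export
calibration_motions <- function() {
  tibble::tribble(
    ~motion_id, ~shape,                ~thumb_rotation, ~thumb_flexion, ~index, ~middle, ~ring_little,
    1L, "thumb_flexion",       0,   1, 0, 0, 0,
    2L, "thumb_abduction",     1,   0, 0, 0, 0,
    3L, "index_flexion",       0,   0, 1, 0, 0,
    4L, "middle_flexion",      0,   0, 0, 1, 0,
    5L, "ring_little_flexion", 0,   0, 0, 0, 1,
    6L, "index_pointer",       0.5, 1, 0, 1, 1,
    7L, "cylindrical_grip",    1,   1, 1, 1, 1,
    8L, "lateral_grip",        0,   1, 1, 1, 1,
    9L, "tripod_grip",         0.5, 1, 1, 1, 0
  )
}

#' @rdname calibration_motions
#' @export
task_shapes <- function() {
  tibble::tribble(
    ~shape,                ~thumb_rotation, ~thumb_flexion, ~index, ~middle, ~ring_little,
    "thumb_abduction",     1,   0, 0, 0, 0,
    "thumb_flexion",       0,   1, 0, 0, 0,
    "index_flexion",       0,   0, 1, 0, 0,
    "middle_flexion",      0,   0, 0, 1, 0,
    "ring_little_flexion", 0,   0, 0, 0, 1,
    "index_pointer",       0.5, 1, 0, 1, 1,
    "cylindrical_grip",    1,   1, 1, 1, 1,
    "lateral_grip",        0,   1, 1, 1, 1,
    "pinch_grip",          0.5, 1, 1, 0, 0
  )
}

# Template posture (named 5-vector) for a calibration motion id.
motion_template <- function(motion_id) {
  motions <- calibration_motions()
  if (!is.numeric(motion_id) || length(motion_id) != 1L ||
      !motion_id %in% motions$motion_id) {
    abort(sprintf(
      "`motion_id` must be a single integer in 1..%d.", max(motions$motion_id)
    ))
  }
  row <- motions[motions$motion_id == motion_id, DOA_NAMES]
  stats::setNames(as.numeric(row), DOA_NAMES)
}
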
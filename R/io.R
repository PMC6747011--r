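# Session serialization: a plain-text CSV + JSON dialect (one directory per
# session: emg.csv, glove.csv, labels.csv, meta.json). All seeds and
# generator parameters are recorded in meta.json.

#' Write / read a calibration session
#'
#' Serializes a `calibration_session` to a directory of CSV files plus a
#' JSON metadata file, and reads it back.
#'
#' @param session A `calibration_session`.
#' @param dir Directory to write (created if missing).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `calibration_session`.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(as.data.frame(session$emg$signal)),
                   file.path(dir, "emg.csv"))
  glove <- session$glove$signal
  colnames(glove) <- sprintf("g%02d", seq_len(ncol(glove)))
  readr::write_csv(tibble::as_tibble(as.data.frame(glove)),
                   file.path(dir, "glove.csv"))
  readr::write_csv(tibble::tibble(label = session$labels),
                   file.path(dir, "labels.csv"))
  readr::write_csv(tibble::as_tibble(session$intent),
                   file.path(dir, "intent.csv"))
  readr::write_csv(session$segments, file.path(dir, "segments.csv"))
  meta <- c(session$meta, list(split = session$split,
                               fs_emg = session$emg$fs,
                               fs_glove = session$glove$fs))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  emg <- as.matrix(readr::read_csv(file.path(dir, "emg.csv"),
                                   show_col_types = FALSE))
  glove <- as.matrix(readr::read_csv(file.path(dir, "glove.csv"),
                                     show_col_types = FALSE))
  labels <- readr::read_csv(file.path(dir, "labels.csv"),
                            show_col_types = FALSE)$label
  intent_df <- readr::read_csv(file.path(dir, "intent.csv"),
                               show_col_types = FALSE)
  segments <- readr::read_csv(file.path(dir, "segments.csv"),
                              show_col_types = FALSE)
  split <- meta$split
  meta$split <- NULL
  structure(
    list(
      emg = emg_recording(emg, meta$fs_emg),
      glove = list(signal = unname(glove), fs = meta$fs_glove),
      labels = as.integer(labels),
      intent = doa_trajectory(as.matrix(intent_df[, DOA_NAMES]),
                              intent_df$time),
      segments = segments,
      split = split,
      meta = meta
    ),
    class = "calibration_session"
  )
}

#' Export a session log as a flat trial table
#'
#' One row per trial (mode, block, trial, posture, MAE, score), the format
#' used for cross-subject statistics.
#'
#' @param log A `session_log`.
#' @param file Optional CSV path; when given the table is also written.
#' @return The trial tibble (invisibly when `file` is given).
#' @export
export_trials <- function(log, file = NULL) {
  out <- tidy.session_log(log)
  if (!is.null(file)) {
    readr::write_csv(out, file)
    return(invisible(out))
  }
  out
}
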
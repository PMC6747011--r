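#' Plot a DOA trajectory
#'
#' @param object A [doa_trajectory()].
#' @param ... Unused.
#' @return A ggplot of the five digit positions over time.
#' @exportS3Method ggplot2::autoplot
autoplot.doa_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(DOA_NAMES),
                              names_to = "doa", values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$position,
                                     colour = .data$doa)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "normalized position",
                  colour = "DOA") +
    ggplot2::theme_minimal()
}

#' Learning curve of a posture-matching session
#'
#' Block means of the trial MAE with per-block spread, the task's learning
#' curve.
#'
#' @param object A `session_log`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.session_log <- function(object, ...) {
  by_block <- dplyr::summarise(dplyr::group_by(object$trials, .data$block),
                               mean_mae = mean(.data$mae),
                               se = sd(.data$mae) / sqrt(dplyr::n()),
                               .groups = "drop")
  ggplot2::ggplot(by_block, ggplot2::aes(.data$block, .data$mean_mae)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_mae - .data$se,
                                      ymax = .data$mean_mae + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(by_block$block)) +
    ggplot2::labs(x = "block", y = "mean MAE",
                  title = sprintf("%s control", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot an adaptation report
#'
#' Principal-component similarity to block 1 and explained-variance curves
#' against the block number.
#'
#' @param object An `adaptation_report` from [analyze_adaptation()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.adaptation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"block",
                              names_to = "measure", values_to = "value")
  long$panel <- ifelse(grepl("^sim", long$measure), "cosine similarity",
                       "% variance explained")
  ggplot2::ggplot(long, ggplot2::aes(.data$block, .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "block", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model-selection trace
#'
#' Validation multivariate R-squared of every candidate evaluated in the
#' three selection stages.
#'
#' @param model A `wiener_model` fitted by [select_and_finalize()].
#' @return A ggplot.
#' @export
plot_selection_trace <- function(model) {
  if (is.null(model$trace)) abort("model carries no selection trace.")
  tr <- model$trace$evaluations
  ggplot2::ggplot(tr, ggplot2::aes(.data$step, .data$r2,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = "evaluation step", y = "validation R2 (multivariate)") +
    ggplot2::theme_minimal()
}
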
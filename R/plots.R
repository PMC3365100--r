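# ggplot2 displays for the main result types.

#' Plot a cross-validation table
#'
#' Cross-validation error against tree size with one-standard-error bars;
#' the dashed line marks the one-SE selection threshold.
#'
#' @param object A `cv_table` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_table <- function(object, ...) {
  m <- which.min(object$cv_error)
  thr <- object$cv_error[m] + object$se[m]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size,
                                       y = .data$cv_error)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$cv_error - .data$se,
                                        ymax = .data$cv_error + .data$se),
                           width = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "tree size (leaves)",
                  y = "cross-validation error",
                  title = "Pruning path cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot a time budget
#'
#' Stacked proportions per habitat and behaviour, faceted by diel phase
#' (and bird when several are present).
#'
#' @param object A `time_budget` from [compute_budget()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.time_budget <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$habitat,
                                    y = .data$proportion,
                                    fill = .data$behaviour)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of fixes",
                  title = "Time-activity budget") +
    ggplot2::theme_minimal()
  if (length(unique(object$bird_id)) > 1) {
    p + ggplot2::facet_grid(bird_id ~ phase)
  } else {
    p + ggplot2::facet_wrap(~phase)
  }
}

#' Plot an acceleration segment
#'
#' Raw (or dynamic) tri-axial series of one 3 s segment.
#'
#' @param segment Tibble with columns `t`, `x`, `y`, `z` (e.g. from
#'   [simulate_segment()]).
#' @param dynamic Plot the dynamic component (static removed) instead of
#'   the raw signal.
#' @return A ggplot.
#' @export
plot_segment <- function(segment, dynamic = FALSE) {
  d <- segment
  if (dynamic) {
    sd_ <- static_dynamic(d$x, d$y, d$z)
    d <- tibble::tibble(t = d$t, x = sd_$dynamic$x, y = sd_$dynamic$y,
                        z = sd_$dynamic$z)
  }
  long <- tidyr::pivot_longer(d, c("x", "y", "z"), names_to = "axis",
                              values_to = "g")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$g,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)",
                  colour = "axis (surge/sway/heave)") +
    ggplot2::theme_minimal()
}
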
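#' Plot a posterior trajectory under accumulating evidence
#'
#' Line plot of the accident-type posteriors against the evidence step, one
#' line per accident type, with the inserted behavior labelling each step.
#'
#' @param object A `prediction_trajectory` from [sequential_prediction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_trajectory
#' @export
autoplot.prediction_trajectory <- function(object, ...) {
  cls <- intersect(accident_types(), names(object))
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(cls),
                              names_to = "accident_type", values_to = "posterior")
  labels <- ifelse(is.na(object$behavior), "none", object$behavior)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$posterior,
                                     colour = .data$accident_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$step, labels = labels) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "evidence inserted", y = "posterior probability",
                  colour = "accident type") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.prediction_trajectory
#' @inheritParams sequential_prediction
#' @export
plot_trajectory <- function(model, ordered_evidence) {
  autoplot.prediction_trajectory(sequential_prediction(model, ordered_evidence))
}

#' Plot a backward-diagnosis trace
#'
#' Shows every eligible behavior's posterior at each diagnosis round, with the
#' selected behavior highlighted and the stop threshold drawn as a dashed
#' line.
#'
#' @param object A `diagnosis_trace` from [critical_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diagnosis_trace
#' @export
autoplot.diagnosis_trace <- function(object, ...) {
  df <- tidy.diagnosis_trace(object)
  if (!nrow(df)) rlang::abort("Diagnosis trace has no candidate rounds to plot.")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$step), y = .data$posterior)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), alpha = 0.8) +
    ggplot2::geom_text(
      data = df[df$selected, , drop = FALSE],
      ggplot2::aes(label = .data$behavior), vjust = -0.8, size = 3
    ) +
    ggplot2::geom_hline(yintercept = object$thresholds[["stop_posterior"]],
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d62728", `FALSE` = "grey55"),
                                 guide = "none") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "diagnosis round",
                  y = sprintf("P(behavior = Yes | %s accident, clamped group)",
                              object$accident_type)) +
    ggplot2::theme_minimal()
}
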
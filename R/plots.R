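#' Plot the preprocessing stages of a record
#'
#' Four stacked panels — filtered signal, normalized signal, first intrinsic
#' mode function, amplitude envelope — the standard diagnostic view of the
#' conditioning chain.
#'
#' @param object A `pcg_stages` tibble from [preprocess_stages()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcg_stages <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stage, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "PCG preprocessing stages") +
    ggplot2::theme_minimal()
}

#' Plot training history of a fitted labeler
#'
#' Accuracy and loss as a function of training epoch.
#'
#' @param object A `pcg_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcg_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Training history (%s)",
                                  object$architecture)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation panel
#'
#' Bar chart of the metric panel per group (auscultation site or dataset).
#'
#' @param object A `pcg_evaluation` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcg_evaluation <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object),
    c("accuracy", "sensitivity", "precision", "specificity", "f1"),
    names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent", title = "Segmentation metrics") +
    ggplot2::theme_minimal()
}

#' Plot a labeled PCG signal
#'
#' The waveform with the phase of every sample shaded, for visual inspection
#' of annotations or predictions.
#'
#' @param rec A [pcg_record()] or numeric signal.
#' @param labels A [label_seq()] or [region_table()] for the same samples.
#' @param rate Sampling rate when `rec` is a bare vector.
#' @return A ggplot object.
#' @export
plot_labeled_record <- function(rec, labels, rate = NULL) {
  if (inherits(rec, "pcg_record")) {
    x <- rec$samples
    rate <- rec$sampling_rate_hz
  } else {
    x <- as.double(rec)
    if (is.null(rate)) abort("`rate` is required for a bare numeric vector.")
  }
  if (inherits(labels, "region_table")) {
    labels <- expand_labels(labels, rate)
  }
  n <- min(length(x), length(labels))
  df <- tibble(time_s = (seq_len(n) - 1L) / rate, value = x[seq_len(n)],
               phase = factor(as.character(labels[seq_len(n)]),
                              levels = PCG_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   colour = .data$phase, group = 1L)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude", colour = "phase") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
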
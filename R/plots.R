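#' @exportS3Method ggplot2::autoplot
autoplot.eeg_record <- function(object, channels = NULL, max_points = 20000, ...) {
  channels <- channels %||% eeg_channels(object)
  df <- as_tibble(object)[, c("time_s", channels)]
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  long <- tidyr::pivot_longer(df, -"time_s", names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value))
  ann <- annotations(object)
  if (!is.null(ann) && nrow(ann) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p + ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)")
}

#' Plot the stages of a detection run
#'
#' Shows the raw classifier margin, the smoothed series with the decision
#' threshold, and the final (collared) binary decisions -- the standard
#' at-a-glance view of what the postprocessing chain did to a recording.
#'
#' @param object A `seizure_detection` tibble from [run_detector()].
#' @param annotations Optional reference intervals to shade.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.seizure_detection <- function(object, annotations = NULL, ...) {
  params <- attr(object, "params")
  long <- dplyr::bind_rows(
    tibble(start_s = object$start_s, value = object$margin, stage = "classifier margin"),
    tibble(start_s = object$start_s, value = object$smoothed, stage = "smoothed"),
    tibble(start_s = object$start_s, value = object$decision, stage = "decision")
  )
  long$stage <- factor(long$stage, levels = c("classifier margin", "smoothed", "decision"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$start_s, y = .data$value))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    p <- p + ggplot2::geom_rect(
      data = annotations,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p + ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(
      data = tibble(stage = factor("smoothed", levels = levels(long$stage)), thr = params$threshold),
      ggplot2::aes(yintercept = .data$thr),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stage), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a center-frequency scan
#'
#' @param scan Tibble from [center_frequency_scan()].
#' @return A ggplot: center frequencies by mode index, one line per K,
#'   non-monotone (over-decomposed) K values dashed.
#' @export
plot_center_frequencies <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(
    x = .data$mode, y = .data$center_freq_hz,
    group = .data$K, colour = factor(.data$K), linetype = .data$monotone
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed")) +
    ggplot2::labs(x = "mode", y = "center frequency (Hz)", colour = "K", linetype = "monotone")
}
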
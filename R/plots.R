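# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot smoothed AU intensity with temporal phases
#'
#' One panel per AU: the smoothed intensity trace over time with frames
#' colored by temporal phase (neutral, onset, apex, offset) and the
#' activation threshold drawn as a reference line.
#'
#' @param intensity Tibble from [au_intensity()].
#' @param aus Optional subset of AU names to display.
#' @param frame_rate Frames per second (scales the time axis).
#' @param threshold Activation threshold to draw.
#' @return A ggplot object.
#' @export
plot_au_intensity <- function(intensity, aus = NULL, frame_rate = 25,
                              threshold = 0.5) {
  d <- intensity
  if (!is.null(aus)) d <- d[d$au %in% aus, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame / frame_rate,
                                  y = .data$smoothed)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line(color = "grey30", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(color = .data$phase), size = 0.6) +
    ggplot2::facet_wrap(~au) +
    ggplot2::labs(x = "time (s)", y = "smoothed AU intensity",
                  color = "phase") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-group facial expressivity
#'
#' Boxplots (with jittered subject points) of FE or EFE by group, the
#' at-a-glance comparison of controls against the Parkinson severity groups.
#'
#' @param expressivity The `expressivity` table of a [run_pipeline()] report.
#' @param metric `"efe"` (baseline-corrected, default) or `"fe"`.
#' @return A ggplot object.
#' @export
plot_expressivity <- function(expressivity, metric = c("efe", "fe")) {
  metric <- match.arg(metric)
  d <- expressivity[is.finite(expressivity[[metric]]), ]
  d$group <- factor(d$group, levels = intersect(c("C", "LP", "IP", "MP"),
                                                unique(d$group)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[metric]],
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot an ECG trace with detected R peaks
#'
#' @param signal Tibble with `time_s`, `value` (e.g. from [read_signal()]).
#' @param peaks `facexpr_rpeaks` tibble from [detect_r_peaks()].
#' @param xlim Optional time range (seconds).
#' @return A ggplot object.
#' @export
plot_ecg_peaks <- function(signal, peaks, xlim = NULL) {
  d <- signal
  p <- tibble(time = peaks$time)
  if (!is.null(xlim)) {
    d <- d[d$time_s >= xlim[1L] & d$time_s <= xlim[2L], ]
    p <- p[p$time >= xlim[1L] & p$time <= xlim[2L], ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = p, ggplot2::aes(xintercept = .data$time),
                        color = "red", alpha = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "ECG") +
    ggplot2::theme_minimal()
}

#' Calibration curve of a Platt fit
#'
#' @param object A `facexpr_platt` object.
#' @param h_range Decision-value range to draw.
#' @param ... Unused.
#' @return A ggplot object showing `P(y = +1 | h)` over `h_range`.
#' @method autoplot facexpr_platt
#' @export
autoplot.facexpr_platt <- function(object, h_range = c(-4, 4), ...) {
  h <- seq(h_range[1L], h_range[2L], length.out = 201L)
  d <- tibble(h = h, p = platt_probability(object, h))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h, y = .data$p)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey60") +
    ggplot2::labs(x = "decision value h",
                  y = "P(y = +1 | h)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
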
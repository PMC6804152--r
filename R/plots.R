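# ggplot2 views of spectra, class summaries and simulated runs.

#' Plot an annotated MS2 spectrum
#'
#' Peak list as a stick spectrum, optionally marking the theoretical
#' fragments of a library record.
#'
#' @param spectrum A one-row spectra tibble.
#' @param record Optional one-row library tibble whose theoretical
#'   fragments are highlighted.
#' @param config An [annotation_config()] (match tolerances for the
#'   highlighting).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, record = NULL,
                          config = annotation_config()) {
  peaks <- as_peaks(spectrum)
  p <- ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = "intensity (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(record)) {
    th <- theoretical_fragments(record, spectrum$polarity[[1]])
    matched <- peaks[purrr::map_lgl(peaks$mz, function(m) {
      any(abs(m - th$mz) <= pmax(config$diag_tol_da,
                                 th$mz * config$ppm_fragment * 1e-6))
    }), ]
    if (nrow(matched) > 0L) {
      p <- p + ggplot2::geom_segment(
        data = matched,
        ggplot2::aes(xend = .data$mz, yend = 0), colour = "#c0392b")
    }
    p <- p + ggplot2::ggtitle(record$name)
  }
  p
}

#' Class-distribution bar chart
#'
#' @param summary A tibble from [summarize_classes()].
#' @return A ggplot object.
#' @export
plot_class_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$percent),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "share of characterized components (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn plot_class_summary autoplot method for annotation tables.
#' @param object An `ms_annotations` tibble.
#' @param ... Unused.
#' @export
autoplot.ms_annotations <- function(object, ...) {
  plot_class_summary(summarize_classes(object))
}

#' Simulated chromatogram with trigger events and knockout shading
#'
#' Draws the summed MS1 signal of the ground-truth mixture over time,
#' shades the knockout windows, and marks MS2 trigger events.
#'
#' @param object A `dda_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dda_run <- function(object, ...) {
  rng <- range(object$mixture$rt)
  grid <- seq(rng[1] - 0.5, rng[2] + 0.5, by = 0.005)
  signal <- purrr::map_dbl(grid, function(t) {
    s <- sum(object$mixture$abundance *
               exp(-((t - object$mixture$rt)^2) / (2 * object$mixture$sigma^2)))
    if (in_windows(t, object$windows)) 0 else s
  })
  df <- tibble::tibble(rt = grid, intensity = signal)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "MS1 signal (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(object$windows) && nrow(object$windows) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_min, xmax = .data$end_min,
                   ymin = -Inf, ymax = Inf),
      fill = "#e74c3c", alpha = 0.15)
  }
  trig <- dplyr::filter(object$trigger_log, .data$decision == "triggered")
  if (nrow(trig) > 0L) {
    p <- p + ggplot2::geom_point(
      data = trig,
      ggplot2::aes(x = .data$time_min, y = .data$intensity),
      colour = "#2c7fb8", size = 0.8)
  }
  p
}

#' Per-abundance-decile recall bar chart
#'
#' @param object A `recovery_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_metrics <- function(object, ...) {
  ggplot2::ggplot(object$decile_recall,
                  ggplot2::aes(x = factor(.data$decile), y = .data$recall)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "abundance decile (1 = least abundant)", y = "recall") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
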
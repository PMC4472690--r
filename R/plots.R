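# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a motion-index series
#'
#' Line plot of the per-frame motion index (fraction of displaced pixels)
#' over time.
#'
#' @param object A `motion_series` tibble from [process_video()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_series <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$timestamp_ms / 1000, y = .data$motion_index)
  ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "time (s)", y = "motion index (fraction of pixels)",
      title = "Per-frame motion index"
    ) +
    ggplot2::theme_minimal()
}

#' Plot window means of a series
#'
#' @param object A `windowed_series` tibble from [window_means()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.windowed_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window, y = .data$mean)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_continuous(breaks = object$window) +
    ggplot2::labs(
      x = "window", y = "window mean",
      title = "Equal-width window means"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a lagged cross-correlation profile
#'
#' Bar chart of the normalized cross-correlation at each lag, with the
#' selected best positive lag highlighted.
#'
#' @param object A `"cross_correlation"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_correlation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = factor(.data$lag), y = .data$correlation, fill = .data$is_best
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "steelblue")) +
    ggplot2::labs(
      x = "lag (windows)", y = "normalized cross-correlation",
      title = "Windowed lagged cross-correlation"
    ) +
    ggplot2::theme_minimal()
}
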
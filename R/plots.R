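#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a p-value series with its divergence point
#'
#' One point per timepoint on a log10 p-value axis, horizontal reference
#' lines at each significance level (dotted 0.05, dashed 0.01 styling) and
#' a vertical line at each detected divergence time.
#'
#' @param object A `divergence_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.divergence_result <- function(object, ...) {
  pv <- object$p_values
  div <- object$divergence
  linetypes <- rep(c("dotted", "dashed", "dotdash"),
                   length.out = nrow(div))
  p <- ggplot2::ggplot(pv, ggplot2::aes(x = .data$time, y = .data$p_value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time", y = "rank-sum p-value",
      title = sprintf("Per-timepoint divergence: %s vs %s",
                      object$groups[1], object$groups[2])
    ) +
    ggplot2::theme_minimal()
  for (i in seq_len(nrow(div))) {
    p <- p + ggplot2::geom_hline(yintercept = div$alpha[i],
                                 linetype = linetypes[i], colour = "grey30")
    if (!is.na(div$divergence_time[i])) {
      p <- p + ggplot2::geom_vline(xintercept = div$divergence_time[i],
                                   linetype = linetypes[i], colour = "red3")
    }
  }
  p
}

#' Bar chart of co-fusion percentages per condition
#'
#' @param object A `cofusion_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cofusion_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition,
                               y = .data$percent_with_marker)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% fusion events with marker") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Overlay detections on a rendered frame
#'
#' @param stack A [frame_stack()].
#' @param detections Detection tibble for the same channel/frame.
#' @param channel,frame Which image to render.
#' @return A ggplot with the frame as a raster and detections circled.
#' @export
plot_detections <- function(stack, detections, channel = 1, frame = 1) {
  img <- frame_matrix(stack, channel, frame)
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(
      data = detections,
      ggplot2::aes(x = .data$x_px, y = .data$y_px),
      shape = 1, colour = "red", size = 3, inherit.aes = FALSE
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Vesicle count over time
#'
#' @param counts Output of [count_vesicles_over_time()].
#' @return A ggplot.
#' @export
plot_vesicle_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$time_s, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "vesicle count") +
    ggplot2::theme_minimal()
}
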
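#' Plot a gait signal with its phase labels
#'
#' Facets the seven channels over time and shades the background by gait
#' phase, so stride structure and event boundaries are visible at a glance.
#'
#' @param object A `gait_signal` tibble.
#' @param channels Channels to show (default all seven).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_signal <- function(object, channels = gait_channels(), ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), dplyr::all_of(c("time", channels))),
    cols = dplyr::all_of(channels), names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = channels)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value))
  if ("label" %in% names(object) && any(!is.na(object$label))) {
    runs <- rle(as.character(object$label))
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    bands <- tibble(
      xmin = object$time[starts], xmax = object$time[ends],
      phase = phase_factor(runs$values)
    )
    bands <- bands[!is.na(bands$phase), ]
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$phase),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "phase") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A `gait_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "grey20") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "classified as", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot per-class classification metrics
#'
#' @param object A `gait_metrics` or `gait_cv`.
#' @param ... Unused.
#' @return A ggplot object with one bar per class and metric (faceted by
#'   condition for a `gait_cv`).
#' @export
autoplot.gait_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("sensitivity", "specificity", "precision", "f_score", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "gait phase", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gait_metrics
#' @export
autoplot.gait_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("sensitivity", "specificity", "precision", "f_score", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "gait phase", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
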
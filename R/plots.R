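#' Volcano plot of a scored screen
#'
#' @param object A `screen_result`.
#' @param q_threshold Highlight genes below this q (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_result <- function(object, q_threshold = 0.05, ...) {
  g <- mutate(object$genes, significant = .data$q < q_threshold)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$score,
                                  y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "normalized log2 fold-change",
                  y = expression(-log[10] ~ p),
                  colour = sprintf("q < %g", q_threshold),
                  title = sprintf("%s screen", object$params$screen)) +
    ggplot2::theme_minimal()
}

#' Plot cell tracks
#'
#' Trajectories in the xy plane, one colour per cell, each track shifted
#' to start at the origin when `centered = TRUE` (the conventional
#' migration rose plot).
#'
#' @param object A `track_set`.
#' @param centered Start every track at the origin (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.track_set <- function(object, centered = TRUE, ...) {
  df <- object |>
    group_by(.data$cell) |>
    arrange(.data$t, .by_group = TRUE) |>
    mutate(x0 = if (centered) .data$x - .data$x[1] else .data$x,
           y0 = if (centered) .data$y - .data$y[1] else .data$y) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$x0, .data$y0,
                                   group = .data$cell,
                                   colour = factor(.data$cell))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot per-step persistence estimates
#'
#' @param object A `persistence_fit`.
#' @param ... Unused.
#' @return A ggplot of the per-step posterior-mean persistence per cell.
#' @export
autoplot.persistence_fit <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(.data$step, .data$q_hat,
                               group = .data$cell,
                               colour = factor(.data$cell))) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "step", y = "posterior-mean persistence") +
    ggplot2::theme_minimal()
}

#' Plot a differentiation axis over the event cloud
#'
#' @param object A `diff_axis`.
#' @param ... Unused.
#' @return A ggplot: 2D density of pooled events with the co-induction
#'   axis drawn through the center.
#' @export
autoplot.diff_axis <- function(object, ...) {
  ev <- object$events
  ch <- object$channels
  span <- 2 * max(object$sdev)
  seg <- tibble(
    x = object$center[1] - span * object$loadings[1],
    xend = object$center[1] + span * object$loadings[1],
    y = object$center[2] - span * object$loadings[2],
    yend = object$center[2] + span * object$loadings[2])
  ggplot2::ggplot(ev, ggplot2::aes(.data[[ch[1]]], .data[[ch[2]]])) +
    ggplot2::geom_bin2d(bins = 60) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          inherit.aes = FALSE, colour = "firebrick",
                          linewidth = 0.8,
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))) +
    ggplot2::labs(x = paste0("log10 ", ch[1]), y = paste0("log10 ", ch[2])) +
    ggplot2::theme_minimal()
}

#' Mean squared displacement plot
#'
#' @param tracks A `track_set`.
#' @param max_lag Largest lag in frames (see [track_msd()]).
#' @return A ggplot of ensemble MSD against lag time with a linear
#'   reference.
#' @export
plot_msd <- function(tracks, max_lag = NULL) {
  m <- track_msd(tracks, max_lag = max_lag)
  ggplot2::ggplot(m, ggplot2::aes(.data$lag_s, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}
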
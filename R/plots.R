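# ggplot2 presentation layer: one autoplot method per result type.

#' Plot the population kernel sum
#'
#' Kernel sum S(t) with the mean and mean+2*sigma synchrony threshold.
#'
#' @param object a [kernel_sum()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.kernel_sum <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$S)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$mu, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "kernel sum",
                  title = sprintf("threshold = mean + 2σ = %.2f",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' Arc diagram of the SP graph
#'
#' Nodes on a line, grouped by region and degree-sorted ([degree_layout()]),
#' radius scaling with degree; arcs connect SP pairs, colored by scope.
#'
#' @param object an `sp_graph`.
#' @param layout optional precomputed [degree_layout()].
#' @param ... passed to [degree_layout()].
#' @return A ggplot.
#' @export
autoplot.sp_graph <- function(object, layout = NULL, ...) {
  if (is.null(layout)) layout <- degree_layout(object, ...)
  ed <- tidy(object)
  ed <- ed[ed$sp_flag, ]
  pos <- setNames(layout$order, layout$cell_id)
  arcs <- NULL
  if (nrow(ed) > 0L) {
    arcs <- purrr::pmap_dfr(
      list(ed$cell_a, ed$cell_b, ed$scope, ed$co_count),
      function(a, b, scope, w) {
        x0 <- pos[[a]]; x1 <- pos[[b]]
        th <- seq(0, pi, length.out = 30)
        tibble(
          x = (x0 + x1) / 2 + abs(x1 - x0) / 2 * cos(th),
          y = abs(x1 - x0) / 2 * sin(th),
          id = paste(a, b), scope = scope, co_count = w
        )
      }
    )
  }
  p <- ggplot2::ggplot()
  if (!is.null(arcs)) {
    p <- p + ggplot2::geom_path(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   colour = .data$scope, linewidth = .data$co_count),
      alpha = 0.6
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 1.2))
  }
  p +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$order, y = 0, size = .data$radius,
                   fill = .data$region),
      shape = 21
    ) +
    ggplot2::scale_size_identity() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a peri-event triggered average
#'
#' Mean with a +/- SEM ribbon and the peak-latency marker.
#'
#' @param object an [event_triggered_average()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eta <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_t, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$peak_latency_s,
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "time from trigger (s)", y = "mean ± SEM") +
    ggplot2::theme_minimal()
}

#' Plot SP-trigger category fractions
#'
#' @param x the result of [classify_sp_triggers()].
#' @return A ggplot bar chart of the four category fractions.
#' @export
plot_trigger_fractions <- function(x) {
  df <- x$fractions
  df$category <- factor(df$category,
                        levels = c("no_change", "post", "pre", "around"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of SPs") +
    ggplot2::theme_minimal()
}
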
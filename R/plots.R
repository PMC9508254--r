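# ggplot2 views of patterns, networks, envelopes and batteries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tree pattern
#'
#' Points at the treetop positions, sized by crown radius when present.
#'
#' @param object A tree pattern.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tree_pattern
#' @export
autoplot.tree_pattern <- function(object, ...) {
  w <- pattern_window(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if ("crown_radius" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$crown_radius),
      alpha = 0.6, colour = "forestgreen"
    ) +
      ggplot2::scale_size_area(name = "crown radius (m)", max_size = 3)
  } else {
    p + ggplot2::geom_point(size = 0.8, colour = "forestgreen")
  }
  p +
    ggplot2::coord_fixed(xlim = w[1:2], ylim = w[3:4], expand = FALSE) +
    ggplot2::labs(
      x = "x (m)", y = "y (m)",
      title = sprintf("Tree pattern (%s)", attr(object, "provenance") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a competition network over the stand
#'
#' Edges drawn between treetops (width mapped to the competition index for
#' weighted networks) and nodes at the tree positions.
#'
#' @param object A `competition_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot competition_network
#' @export
autoplot.competition_network <- function(object, ...) {
  nodes <- object$nodes
  seg <- dplyr::left_join(
    object$edges,
    dplyr::rename(nodes[, c("id", "x", "y")], xend = "x", yend = "y"),
    by = c(to = "id")
  )
  seg <- dplyr::left_join(
    seg, nodes[, c("id", "x", "y")],
    by = c(from = "id")
  )
  p <- ggplot2::ggplot()
  p <- if ("weight" %in% names(seg)) {
    p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linewidth = .data$weight
      ),
      alpha = 0.3, colour = "grey30"
    ) +
      ggplot2::scale_linewidth(range = c(0.1, 1.2), name = "CI")
  } else {
    p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linewidth = 0.2, alpha = 0.4, colour = "grey30"
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "forestgreen", size = 1
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (m)", y = "y (m)",
      title = sprintf("%s network", toupper(object$net_type))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo envelope
#'
#' Shaded min-max simulation band with the observed curve (if any) on top.
#'
#' @param object A [mc_envelope()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crownet_envelope
#' @export
autoplot.crownet_envelope <- function(object, ...) {
  stat <- attr(object, "statistic")
  lab <- if (stat == "L") {
    if (isTRUE(attr(object, "centered"))) "L(r) - r" else "L(r)"
  } else {
    "g(r)"
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean),
      colour = "steelblue", linetype = 2
    )
  if ("observed" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black")
  }
  p +
    ggplot2::labs(
      x = "r (m)", y = lab,
      title = sprintf(
        "%s envelope, %d simulations of %s", lab,
        attr(object, "n_sim"), attr(object, "null_model")$model
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an interpolated metric field
#'
#' @param object A [interpolate_metric()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crownet_field
#' @export
autoplot.crownet_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Boxplots of a battery metric across null models
#'
#' @param batch A [run_null_battery()] result.
#' @param metric Metric column to plot.
#' @param net_type Optional filter to one network type; with several types
#'   present the plot is faceted.
#' @return A ggplot.
#' @export
plot_battery <- function(batch, metric = "k", net_type = NULL) {
  if (!is.null(net_type)) batch <- batch[batch$net_type %in% net_type, ]
  batch$value <- batch[[metric]]
  batch <- batch[is.finite(batch$value), ]
  ggplot2::ggplot(batch, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::facet_wrap(~net_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
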
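#' Plot a particle-analysis overlay
#'
#' Renders the overlay mask the way the summary images are drawn: accepted
#' particles coloured by their number (and labelled at their centroid),
#' rejected particles white and unnumbered, background dark.
#'
#' @param object An `fc_particles` result from [analyze_particles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_particles <- function(object, ...) {
  ov <- object$overlay
  df <- tibble(
    x = rep(seq_len(ncol(ov)), each = nrow(ov)),
    y = rep(seq_len(nrow(ov)), times = ncol(ov)),
    code = as.vector(ov)
  )
  df <- df[df$code != 0, , drop = FALSE]
  df$fill <- ifelse(df$code < 0, NA_integer_, df$code)
  labels <- object$records[object$records$accepted, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$fill))) +
    ggplot2::scale_fill_hue(na.value = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void() +
    ggplot2::theme(panel.background = ggplot2::element_rect(fill = "grey10"))
  if (nrow(labels) > 0) {
    p <- p + ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y, label = .data$number),
      colour = "white", size = 3
    )
  }
  p
}

#' Plot the per-class counts of a classification run
#'
#' @param object An `fc_run` from [classify()].
#' @param ... Unused.
#' @return A ggplot bar chart of viable/apoptotic/necrotic counts.
#' @export
autoplot.fc_run <- function(object, ...) {
  df <- tibble(
    class = factor(c("viable", "apoptotic", "necrotic"),
      levels = c("viable", "apoptotic", "necrotic")
    ),
    count = c(object$counts$viable, object$counts$apoptotic, object$counts$necrotic)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count, fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      viable = "#2e7d32", apoptotic = "#f9a825", necrotic = "#c62828"
    )) +
    ggplot2::labs(
      x = NULL, y = "cells",
      title = sprintf("mode %s: %d cells total", object$config$mode, object$counts$total)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene's channels
#'
#' Displays the green and red planes side by side with the ground-truth
#' cell outlines.
#'
#' @param object The list returned by [generate_scene()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot_scene <- function(object, ...) {
  stack <- object$stack
  to_df <- function(plane, channel) {
    m <- unclass(plane)
    tibble(
      x = rep(seq_len(ncol(m)), each = nrow(m)),
      y = rep(seq_len(nrow(m)), times = ncol(m)),
      intensity = as.vector(m), channel = channel
    )
  }
  df <- dplyr::bind_rows(to_df(stack$green, "6-CF (green)"), to_df(stack$red, "AnnCy3 (red)"))
  truth <- object$truth
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::geom_point(
      data = truth,
      ggplot2::aes(x = .data$cx, y = .data$cy, colour = .data$class),
      shape = 1, size = 3
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}
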
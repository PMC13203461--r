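#' Path and density visualization of gaze on one item
#'
#' Two-panel figure for a single face item across participants: a scatter of
#' fixations coloured by within-participant temporal order with per-
#' participant path lines and the zone rectangles, next to a 2-D density
#' heatmap of all fixations. Output is deterministic given fixed input.
#'
#' @param sequences A labelled sequence tibble from [build_sequences()].
#' @param layout The AOI layout.
#' @param item Item identifier to plot.
#' @param file Optional path; when given the figure is written there with
#'   [ggplot2::ggsave()] (format from the extension, e.g. `.png`, `.svg`).
#' @return A patchwork object combining the two panels (invisibly when
#'   `file` is given).
#' @export
render_paths <- function(sequences, layout, item, file = NULL) {
  fx <- sequences[sequences$item == item, , drop = FALSE]
  if (nrow(fx) == 0) stop("no fixations for item '", item, "'", call. = FALSE)
  lz <- layout[layout$item == item, ]
  if (nrow(lz) == 0) stop("no layout for item '", item, "'", call. = FALSE)

  base <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = lz,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::scale_y_reverse() +  # screen coordinates: y grows downward
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")

  p_path <- base +
    ggplot2::geom_path(
      data = fx,
      ggplot2::aes(.data$x_px, .data$y_px, group = .data$participant),
      alpha = 0.25, colour = "grey60") +
    ggplot2::geom_point(
      data = fx,
      ggplot2::aes(.data$x_px, .data$y_px, colour = .data$ord),
      size = 1.2, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "fixation\norder") +
    ggplot2::ggtitle(paste("Gaze paths:", item))

  p_heat <- base +
    ggplot2::stat_density_2d(
      data = fx,
      ggplot2::aes(.data$x_px, .data$y_px, fill = ggplot2::after_stat(density)),
      geom = "raster", contour = FALSE) +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::ggtitle("Gaze density")

  fig <- patchwork::wrap_plots(p_path, p_heat, ncol = 2)
  if (!is.null(file)) {
    ggplot2::ggsave(file, fig, width = 10, height = 4.5, dpi = 150)
    return(invisible(fig))
  }
  fig
}

#' Heatmap of a transition matrix
#'
#' Tile plot of the conditional transition probabilities of a fitted or
#' reference transition model, annotated with the probability values.
#'
#' @param model A `transition_model` or `fixture_matrix`.
#' @return A ggplot object.
#' @export
plot_transition_matrix <- function(model) {
  P <- model$prob
  df <- tibble::as_tibble(as.data.frame.table(P, responseName = "p"))
  names(df)[1:2] <- c("context", "destination")
  ggplot2::ggplot(df, ggplot2::aes(.data$destination, .data$context,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$p)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P") +
    ggplot2::labs(x = "next zone", y = "context",
                  title = sprintf("Order-%d transition probabilities",
                                  model$order)) +
    ggplot2::theme_minimal()
}
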
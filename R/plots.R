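#' Plot a B-scan as a raster
#' @param b a [bscan()].
#' @param trans intensity transform for display ("sqrt", "log1p", "identity").
#' @return A ggplot object (depth on a reversed y axis, µm axes).
#' @export
plot_bscan <- function(b, trans = c("sqrt", "log1p", "identity")) {
  b <- as_bscan(b)
  trans <- match.arg(trans)
  f <- switch(trans, sqrt = sqrt, log1p = log1p, identity = identity)
  df <- tidyr::expand_grid(z = seq_len(nrow(b$pixels)),
                           x = seq_len(ncol(b$pixels)))
  df$intensity <- as.vector(b$pixels)
  df$depth_um <- (df$z - 1) * b$axial_pitch
  df$lateral_um <- (df$x - 1) * b$lateral_pitch
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_um, .data$depth_um,
                                   fill = f(.data$intensity))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (µm)", y = "depth (µm)",
                  title = b$id) +
    ggplot2::theme_minimal()
}

#' Plot a normalized depth-intensity profile
#' @param object a `depth_profile` from [average_profile()].
#' @param ... unused.
#' @return A ggplot object with detected peaks marked.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, ...) {
  df <- tibble::tibble(
    depth_um = (seq_along(object$values) - 1) * object$axial_pitch,
    intensity = object$values)
  pk <- tibble::tibble(
    depth_um = (object$peak_indices - 1) * object$axial_pitch,
    intensity = object$values[object$peak_indices])
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_um, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "red", size = 2) +
    ggplot2::labs(x = "flattened depth (µm)",
                  y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Box-plot of per-stage enamel metrics
#'
#' One box per treatment stage with the per-subject metrics overlaid — the
#' standard 3D-box-plot-style group summary flattened to 2D.
#'
#' @param object a `group_stats` from [run_group_stats()] (or a
#'   `group_summary`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot group_stats
#' @export
autoplot.group_stats <- function(object, ...) {
  m <- object$matrix
  labs <- colnames(m) %||% paste("stage", seq_len(ncol(m)))
  df <- tibble::tibble(
    stage = factor(rep(labs, each = nrow(m)), levels = labs),
    metric_um = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$metric_um)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "enamel metric (µm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @method autoplot group_summary
#' @export
autoplot.group_summary <- function(object, ...) {
  autoplot.group_stats(object, ...)
}

#' Render an RGB overlay array with grid graphics
#' @param overlay H x W x 3 array in 0..1 (from [sobel_overlay()],
#'   [compose_overlay()], or `quantized_rgb`).
#' @return The rasterGrob, drawn as a side effect.
#' @export
plot_overlay <- function(overlay) {
  grid::grid.newpage()
  g <- grid::rasterGrob(overlay, interpolate = FALSE)
  grid::grid.draw(g)
  invisible(g)
}
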
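#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Long tibble of pixels for raster plotting.
frame_to_long <- function(values) {
  d <- dim(values)
  tibble::tibble(
    x = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    y = rep(rep(seq_len(d[1]), times = d[2]), d[3]),
    layer = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(values)
  )
}

#' Plot a motion map
#'
#' Single-layer maps render as a greyscale raster; 3-layer maps render
#' one panel per layer. y increases downwards, matching image
#' coordinates.
#'
#' @param object A [motion_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motion_map <- function(object, ...) {
  df <- frame_to_long(object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("motion map (%s)", object$method),
                  fill = "value") +
    ggplot2::theme_minimal()
  if (dim(object$values)[3] == 3L) {
    p <- p + ggplot2::facet_wrap(~layer, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a flow field as a sparse arrow field
#'
#' @param object A [flow_field()].
#' @param stride Plot an arrow every `stride` pixels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_field <- function(object, stride = 8, ...) {
  h <- nrow(object$vx)
  w <- ncol(object$vx)
  ys <- seq(1, h, by = stride)
  xs <- seq(1, w, by = stride)
  df <- tidyr::expand_grid(y = ys, x = xs)
  df$vx <- object$vx[cbind(df$y, df$x)]
  df$vy <- object$vy[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + .data$vx, yend = .data$y + .data$vy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "optical flow (pixel displacement)") +
    ggplot2::theme_minimal()
}

#' Plot per-class AP against the IOU threshold
#'
#' @param object A [map_suite()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.map_eval <- function(object, ...) {
  ggplot2::ggplot(
    object$per_class,
    ggplot2::aes(.data$iou_thresh, .data$ap,
                 colour = factor(.data$class_id),
                 group = factor(.data$class_id))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IOU threshold", y = "average precision",
                  colour = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Tidy / glance a PCA colour model
#'
#' @param x A [fit_pca_color()] model.
#' @param ... Unused.
#' @return `tidy()`: one row per (component, channel) coefficient;
#'   `glance()`: one-row summary of the fit.
#' @export
tidy.pca_color_model <- function(x, ...) {
  tibble::tibble(
    component = rep(c("p1", "p2"), each = 3),
    channel = rep(c("R", "G", "B"), times = 2),
    coefficient = as.vector(x$components)
  )
}

#' @rdname tidy.pca_color_model
#' @export
glance.pca_color_model <- function(x, ...) {
  tibble::tibble(
    n_images_sampled = x$n_images_sampled,
    seed = x$seed,
    whitening_scale_1 = x$whitening_scale[1],
    whitening_scale_2 = x$whitening_scale[2]
  )
}
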
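#' Interpolate per-channel values over the schematic head disc
#'
#' Inverse-distance-weighted interpolation of one scalar per channel onto a
#' regular grid masked to the unit disc. Channels with missing values are
#' excluded from the interpolation.
#'
#' @param values A tibble/data frame with columns `channel` and `value`, or
#'   a named numeric vector.
#' @param layout Layout tibble from [montage_layout()].
#' @param grid_n Grid resolution per axis (default 60).
#' @param power Inverse-distance exponent (default 2).
#' @return A tibble `x`, `y`, `value` covering the disc.
#' @export
interpolate_topomap <- function(values, layout = montage_layout(),
                                grid_n = 60, power = 2) {
  values <- as_channel_values(values, layout)
  ok <- is.finite(values$value)
  if (!any(ok)) stop("no finite channel values to interpolate")
  pts <- values[ok, ]
  ax <- seq(-1, 1, length.out = grid_n)
  grid <- expand.grid(x = ax, y = ax)
  grid <- grid[grid$x^2 + grid$y^2 <= 1, ]
  d2 <- outer(grid$x, pts$x, "-")^2 + outer(grid$y, pts$y, "-")^2
  w <- 1 / pmax(d2, 1e-12)^(power / 2)
  field <- as.vector((w %*% pts$value) / rowSums(w))
  tibble::tibble(x = grid$x, y = grid$y, value = field)
}

as_channel_values <- function(values, layout) {
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::tibble(channel = names(values), value = unname(values))
  }
  unknown <- setdiff(values$channel, layout$channel)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  dplyr::left_join(layout, values[c("channel", "value")], by = "channel")
}

#' Scalp topography of one value per channel
#'
#' Draws the interpolated field over a schematic head (unit disc, nose up)
#' with channel markers and labels. The geometry is schematic, not
#' anatomical; the map is meant for qualitative inspection of which
#' channels carry an effect.
#'
#' @inheritParams interpolate_topomap
#' @param title Optional plot title.
#' @return A ggplot.
#' @export
plot_topomap <- function(values, layout = montage_layout(), grid_n = 60,
                         title = NULL) {
  field <- interpolate_topomap(values, layout, grid_n)
  pts <- as_channel_values(values, layout)
  theta <- seq(0, 2 * pi, length.out = 181)
  outline <- tibble::tibble(x = cos(theta), y = sin(theta))
  nose <- tibble::tibble(x = c(-0.08, 0, 0.08), y = c(0.995, 1.1, 0.995))
  ggplot2::ggplot(field, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = outline, linewidth = 0.6) +
    ggplot2::geom_path(data = nose, linewidth = 0.6) +
    ggplot2::geom_point(data = pts, shape = 21, fill = "white", size = 2) +
    ggplot2::geom_text(data = pts, ggplot2::aes(label = .data$channel),
                       nudge_y = 0.09, size = 2.6) +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
}

#' Render a topographic map to an image file
#'
#' @inheritParams plot_topomap
#' @param out_path Output image path (extension selects the device, e.g.
#'   `.png`).
#' @param width,height,dpi Device size in inches and resolution.
#' @return `out_path`, invisibly.
#' @export
render_topomap <- function(values, layout = montage_layout(), out_path,
                           title = NULL, width = 4, height = 4, dpi = 150) {
  p <- plot_topomap(values, layout, title = title)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}
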
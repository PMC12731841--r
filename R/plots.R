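# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a texture map
#'
#' Valid blocks are drawn as tiles on the block grid; invalid blocks are
#' left blank.
#'
#' @param object A [texture_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot texture_map
#' @export
autoplot.texture_map <- function(object, ...) {
  d <- as_tibble.texture_map(object)
  d <- d[d$valid & is.finite(d$value), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = object$feature) +
    ggplot2::labs(
      title = paste(object$family, object$feature, "texture map"),
      x = "block column", y = "block row") +
    ggplot2::theme_minimal()
}

#' Plot a phantom image with its masks
#'
#' @param object A `phantom` from [gen_histology_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom
#' @export
autoplot.phantom <- function(object, ...) {
  px <- object$image$pixels
  d <- tibble::tibble(
    row = as.integer(row(px)), col = as.integer(col(px)),
    intensity = as.numeric(px),
    damaged = as.logical(object$damaged_mask$mask))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::geom_point(
      data = d[d$damaged & (d$row + d$col) %% 14 == 0, ],
      colour = "red", size = 0.1, alpha = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Phantom (%s, damaged %.1f%%)",
                                  object$spec$group,
                                  100 * object$realized_fraction),
                  x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_void()
}

#' Group comparison plot for one feature
#'
#' Points per subject with group mean cross-bars, the usual presentation
#' of per-group feature values.
#'
#' @param table Long data frame with `subject`, `group`, `feature`,
#'   `value`.
#' @param feature Feature to plot.
#' @return A ggplot object.
#' @export
plot_group_feature <- function(table, feature) {
  d <- table[table$feature == feature, , drop = FALSE]
  if (nrow(d) == 0L) stop("feature not found", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::labs(title = feature, x = NULL, y = "value") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a DCE enhancement curve
#'
#' @param curve A tibble from [percent_enhancement()].
#' @return A ggplot object.
#' @export
plot_enhancement <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time,
                                      y = .data$enhancement_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "signal enhancement (%)") +
    ggplot2::theme_classic()
}
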
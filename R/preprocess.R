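#' Downsample an image by block averaging
#'
#' Reduces each image dimension by an integer factor; each output pixel is
#' the mean of its `factor x factor` input block (per channel). Trailing
#' rows/columns that do not fill a block are dropped, and the physical pixel
#' spacing is multiplied by the factor. High-magnification slides are
#' typically reduced 10-fold before texture analysis.
#'
#' @param img A [raster_image()].
#' @param factor Positive integer downsampling factor.
#' @return A [raster_image()] of size `floor(dim / factor)`.
#' @export
downsample <- function(img, factor) {
  stopifnot(inherits(img, "raster_image"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != as.integer(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  d <- dim(img$pixels)
  if (any(d[1:2] < factor)) {
    stop("image dimensions must be at least `factor`", call. = FALSE)
  }
  block_mean <- function(m) {
    nr <- (nrow(m) %/% factor) * factor
    nc <- (ncol(m) %/% factor) * factor
    m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
    # collapse rows then columns
    m <- rowsum(m, rep(seq_len(nr %/% factor), each = factor)) / factor
    m <- t(rowsum(t(m), rep(seq_len(nc %/% factor), each = factor)) / factor)
    dimnames(m) <- NULL
    m
  }
  px <- if (length(d) == 3L) {
    out <- lapply(seq_len(d[3L]), function(k) block_mean(img$pixels[, , k]))
    array(unlist(out), dim = c(dim(out[[1L]]), d[3L]))
  } else {
    block_mean(img$pixels)
  }
  raster_image(px, img$pixel_spacing * factor, img$provenance)
}

#' Convert an RGB image to grayscale
#'
#' Applies the ITU-R BT.601 luminance weights (0.2989 R + 0.5870 G +
#' 0.1140 B). A scalar (already-gray) image is returned unchanged.
#'
#' @param img A [raster_image()] with 1 or 3 channels.
#' @return A single-channel [raster_image()].
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  nc <- n_channels(img)
  if (nc == 1L) return(img)
  if (nc != 3L) {
    stop(sprintf("expected 1 or 3 channels, got %d", nc), call. = FALSE)
  }
  px <- 0.2989 * img$pixels[, , 1L] +
        0.5870 * img$pixels[, , 2L] +
        0.1140 * img$pixels[, , 3L]
  px <- matrix(px, dim(img$pixels)[1L], dim(img$pixels)[2L])
  raster_image(px, img$pixel_spacing, img$provenance)
}

#' Rescale image intensities to a fixed range
#'
#' Per-image min-max normalisation to `[0, 255]`, applied before gray-level
#' quantization so slides digitised under different exposure settings share
#' a common intensity scale. A constant image is mapped to 0.
#'
#' @param img A single-channel [raster_image()].
#' @return A [raster_image()] with intensities in `[0, 255]`.
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) != 1L) {
    stop("normalisation expects a grayscale image", call. = FALSE)
  }
  px <- img$pixels
  rng <- range(px)
  px <- if (rng[2L] > rng[1L]) (px - rng[1L]) / (rng[2L] - rng[1L]) * 255
        else px * 0
  raster_image(px, img$pixel_spacing, img$provenance)
}

#' Quantized gray-level image
#'
#' The common substrate of all four texture matrix families: a grid of
#' 1-based integer gray levels inside the ROI (0 outside), with the bin
#' edges and gray-level count retained as metadata.
#'
#' @param levels Integer matrix of gray levels (0 outside the ROI).
#' @param Ng Number of gray levels.
#' @param bin_edges Numeric vector of `Ng + 1` strictly increasing edges.
#' @param pixel_spacing Micrometres per pixel.
#' @return An object of class `quantized_image`.
#' @export
quantized_image <- function(levels, Ng, bin_edges, pixel_spacing) {
  stopifnot(is.matrix(levels), Ng >= 1, length(bin_edges) == Ng + 1)
  if (any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  inroi <- levels > 0L
  if (any(levels[inroi] > Ng)) {
    stop("levels exceed Ng inside the ROI", call. = FALSE)
  }
  structure(
    list(levels = levels, Ng = as.integer(Ng), bin_edges = bin_edges,
         pixel_spacing = pixel_spacing),
    class = "quantized_image"
  )
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf(
    "<quantized_image> %d x %d px, Ng = %d, %d in-ROI pixel(s), %.3g um/px\n",
    nrow(x$levels), ncol(x$levels), x$Ng, sum(x$levels > 0L),
    x$pixel_spacing))
  invisible(x)
}

#' Quantize in-ROI intensities into equal-width gray-level bins
#'
#' Bins span the min-max of the in-ROI intensities with `Ng` equal-width
#' bins; each in-ROI pixel receives its 1-based bin index, out-of-ROI
#' pixels are 0. A constant ROI maps every pixel to level 1 (with `Ng`
#' still recorded, so downstream matrices keep their nominal shape).
#'
#' @param img A single-channel [raster_image()].
#' @param roi An [roi_mask()] (or logical matrix) with >= 1 true pixel.
#' @param Ng Number of gray levels (>= 2; default 32).
#' @return A [quantized_image()].
#' @export
quantize <- function(img, roi, Ng = 32L) {
  stopifnot(inherits(img, "raster_image"))
  if (n_channels(img) != 1L) {
    stop("quantization expects a grayscale image", call. = FALSE)
  }
  if (Ng < 2L) stop("`Ng` must be at least 2", call. = FALSE)
  m <- as_mask_matrix(roi, dim(img$pixels))
  if (!any(m)) stop("ROI is empty", call. = FALSE)
  Ng <- as.integer(Ng)
  px <- img$pixels
  vals <- px[m]
  rng <- range(vals)
  lv <- matrix(0L, nrow(px), ncol(px))
  if (rng[2L] > rng[1L]) {
    edges <- seq(rng[1L], rng[2L], length.out = Ng + 1L)
    lv[m] <- pmin.int(
      pmax.int(findInterval(vals, edges, rightmost.closed = TRUE), 1L), Ng)
  } else {
    # degenerate range: everything in bin 1; synthesise valid edges
    edges <- rng[1L] + seq(-0.5, 0.5, length.out = Ng + 1L)
    lv[m] <- 1L
  }
  quantized_image(lv, Ng, edges, img$pixel_spacing)
}
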
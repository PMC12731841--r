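#' Raster image container
#'
#' A minimal in-memory container for a histology image: a numeric matrix
#' (grayscale) or a 3-channel array (RGB), together with the physical pixel
#' spacing in micrometres per pixel (isotropic).
#'
#' @param pixels Numeric matrix (`nrow x ncol`) or array (`nrow x ncol x 3`).
#' @param pixel_spacing Pixel spacing in micrometres per pixel; must be > 0.
#' @param provenance Free-text note on where the image came from.
#'
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_spacing, provenance = "") {
  if (is.null(dim(pixels)) || !length(dim(pixels)) %in% c(2L, 3L)) {
    stop("`pixels` must be a 2D matrix or a 3D (RGB) array", call. = FALSE)
  }
  if (length(dim(pixels)) == 3L && dim(pixels)[3L] != 3L) {
    stop("3D pixel arrays must have exactly 3 channels", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    stop("`pixel_spacing` must be a single positive number (um/pixel)",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         provenance = provenance),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3L) d[3L] else 1L
  cat(sprintf("<raster_image> %d x %d px, %d channel(s), %.3g um/px\n",
              d[1L], d[2L], ch, x$pixel_spacing))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

n_channels <- function(img) {
  d <- dim(img$pixels)
  if (length(d) == 3L) d[3L] else 1L
}

#' Region-of-interest mask
#'
#' A binary mask aligned pixel-for-pixel with a [raster_image()]. Labels
#' follow the two regions segmented on each slide (whole tumour and
#' cell-damage areas); anything else is `"custom"`.
#'
#' @param mask Logical matrix, same shape as the image it annotates.
#' @param label One of `"whole_tumor"`, `"damaged"`, `"custom"`.
#'
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("custom", "whole_tumor", "damaged")) {
  label <- match.arg(label)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- if (is.logical(mask)) mask else mask > 0
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s', %d x %d px, %d in-ROI pixel(s)\n",
              x$label, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

as_mask_matrix <- function(roi, dims) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!is.matrix(m)) stop("ROI must be an `roi_mask` or a logical matrix",
                          call. = FALSE)
  if (!identical(dim(m), dims[1:2])) {
    stop("ROI mask shape does not match the image", call. = FALSE)
  }
  if (is.logical(m)) m else m > 0
}

#' Read an image from disk
#'
#' Reads a grayscale or RGB image stored as TIFF or PNG. Intensities are
#' rescaled to the 0-255 range (both formats decode to 0-1 in R); an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_spacing Physical pixel spacing in micrometres per pixel.
#'   Scanner metadata is not parsed, so the spacing must be supplied.
#'
#' @return A [raster_image()].
#' @export
load_image <- function(path, pixel_spacing) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(px)[3L] == 2L) px <- px[, , 1L]                 # gray + alpha
    if (length(dim(px)) == 3L && dim(px)[3L] == 1L) px <- px[, , 1L]
  }
  raster_image(px * 255, pixel_spacing, provenance = path)
}

#' Write an image to disk
#'
#' Counterpart of [load_image()]: intensities are clamped to 0-255 and
#' written as TIFF or PNG according to the file extension.
#'
#' @param img A [raster_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  px <- pmin(pmax(img$pixels / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' Read a binary mask from disk
#'
#' Reads a co-registered binary mask stored as TIFF or PNG; any pixel with
#' value > 0 is in the region.
#'
#' @inheritParams load_image
#' @param label Region label, see [roi_mask()].
#' @return An [roi_mask()].
#' @export
load_mask <- function(path, label = "custom") {
  img <- load_image(path, pixel_spacing = 1)
  px <- img$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  roi_mask(px > 0, label = label)
}
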
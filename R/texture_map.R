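# Windowed texture maps: tile an ROI into fixed physical-size blocks,
# compute per-block features, and summarise each feature map by its median.

#' Tile an ROI into square blocks of fixed physical size
#'
#' The grid is anchored at the top-left of the ROI bounding box; blocks are
#' non-overlapping. A block is admitted when its in-ROI pixel coverage is
#' at least `min_coverage`.
#'
#' @param q A [quantized_image()] (supplies the pixel spacing).
#' @param roi An [roi_mask()] or logical matrix.
#' @param block_mm Block side length in millimetres (default 0.5).
#' @param min_coverage Minimum in-ROI fraction for a block to be valid
#'   (default 0.5).
#' @return An object of class `block_grid`: a tibble of blocks (`row`,
#'   `col`, pixel window `r0:r1 x c0:c1`, `n_roi`, `coverage`, `valid`)
#'   plus grid metadata.
#' @export
tile_roi <- function(q, roi, block_mm = 0.5, min_coverage = 0.5) {
  stopifnot(inherits(q, "quantized_image"))
  m <- as_mask_matrix(roi, dim(q$levels))
  if (!any(m)) stop("ROI is empty", call. = FALSE)
  block_px <- as.integer(round(block_mm * 1000 / q$pixel_spacing))
  if (block_px < 2L) {
    stop("block size is under 2 pixels at this pixel spacing", call. = FALSE)
  }
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  nbr <- (rows[2L] - rows[1L] + 1L) %/% block_px
  nbc <- (cols[2L] - cols[1L] + 1L) %/% block_px
  if (nbr < 1L || nbc < 1L) {
    warning("block size exceeds the ROI bounding box; no valid blocks")
    blocks <- tibble::tibble(
      row = integer(), col = integer(), r0 = integer(), r1 = integer(),
      c0 = integer(), c1 = integer(), n_roi = integer(),
      coverage = numeric(), valid = logical())
  } else {
    grid <- expand.grid(col = seq_len(nbc), row = seq_len(nbr))
    r0 <- rows[1L] + (grid$row - 1L) * block_px
    c0 <- cols[1L] + (grid$col - 1L) * block_px
    n_roi <- mapply(function(r, c) {
      sum(m[r:(r + block_px - 1L), c:(c + block_px - 1L)])
    }, r0, c0)
    coverage <- n_roi / block_px^2
    blocks <- tibble::tibble(
      row = as.integer(grid$row), col = as.integer(grid$col),
      r0 = as.integer(r0), r1 = as.integer(r0 + block_px - 1L),
      c0 = as.integer(c0), c1 = as.integer(c0 + block_px - 1L),
      n_roi = as.integer(n_roi), coverage = coverage,
      valid = coverage >= min_coverage)
  }
  structure(
    list(blocks = blocks, block_mm = block_mm, block_px = block_px,
         n_rows = max(nbr, 0L), n_cols = max(nbc, 0L),
         min_coverage = min_coverage),
    class = "block_grid"
  )
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf(
    "<block_grid> %d x %d blocks of %g mm (%d px), %d valid\n",
    x$n_rows, x$n_cols, x$block_mm, x$block_px, sum(x$blocks$valid)))
  invisible(x)
}

#' Texture map container
#'
#' One feature's per-block values over a [tile_roi()] grid, with a
#' validity mask marking admitted blocks.
#'
#' @param feature Feature display name.
#' @param family Matrix family of the feature.
#' @param values Numeric matrix (`n_rows x n_cols` of the block grid).
#' @param valid Logical matrix, same shape.
#' @param block_mm Block size in millimetres.
#' @return An object of class `texture_map`.
#' @export
texture_map <- function(feature, family, values, valid, block_mm) {
  stopifnot(is.matrix(values), is.matrix(valid),
            identical(dim(values), dim(valid)))
  structure(
    list(feature = feature, family = family, values = values,
         valid = valid, block_mm = block_mm),
    class = "texture_map"
  )
}

#' @export
print.texture_map <- function(x, ...) {
  cat(sprintf("<texture_map> %s %s: %d x %d blocks (%d valid), %g mm\n",
              x$family, x$feature, nrow(x$values), ncol(x$values),
              sum(x$valid), x$block_mm))
  invisible(x)
}

#' @rdname texture_map
#' @param x A `texture_map`.
#' @param ... Unused.
#' @method as_tibble texture_map
#' @export
as_tibble.texture_map <- function(x, ...) {
  tibble::tibble(
    family = x$family, feature = x$feature,
    row = as.integer(row(x$values)), col = as.integer(col(x$values)),
    value = as.numeric(x$values), valid = as.logical(x$valid))
}

#' Compute per-block texture maps
#'
#' Runs the full first-pass extraction inside every valid block of the
#' grid and assembles one map per requested feature. Blocks inherit the
#' whole-ROI gray-level quantization, so values are comparable across the
#' map; gray levels are never re-derived per block.
#'
#' @param q A [quantized_image()].
#' @param roi ROI used for tiling (an [roi_mask()] or logical matrix).
#' @param grid A [tile_roi()] result for this image/ROI.
#' @param features Character vector of feature display names (default all
#'   59); unknown names are an error.
#' @param params A [texture_params()].
#' @return A named list of [texture_map()] objects (`"FAMILY feature"`).
#' @export
compute_texture_map <- function(q, roi, grid, features = NULL,
                                params = texture_params()) {
  stopifnot(inherits(q, "quantized_image"), inherits(grid, "block_grid"))
  m <- as_mask_matrix(roi, dim(q$levels))
  catalog <- feature_names()
  catalog_keys <- paste(catalog$family, catalog$feature)
  if (is.null(features)) {
    features <- catalog_keys
  } else {
    bad <- setdiff(features, c(catalog_keys, catalog$feature))
    if (length(bad) > 0L) {
      stop("unknown feature name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    # bare feature names select every family that defines them
    features <- catalog_keys[catalog$feature %in% features |
                               catalog_keys %in% features]
  }
  nbr <- grid$n_rows; nbc <- grid$n_cols
  valid <- matrix(FALSE, nbr, nbc)
  store <- matrix(NA_real_, length(catalog_keys), nbr * nbc)
  rownames(store) <- catalog_keys
  bl <- grid$blocks[grid$blocks$valid, , drop = FALSE]
  for (k in seq_len(nrow(bl))) {
    b <- bl[k, ]
    sub_lv <- q$levels[b$r0:b$r1, b$c0:b$c1, drop = FALSE]
    sub_m <- m[b$r0:b$r1, b$c0:b$c1, drop = FALSE]
    sub_lv[!sub_m] <- 0L
    if (!any(sub_lv > 0L)) next
    sub_q <- quantized_image(sub_lv, q$Ng, q$bin_edges, q$pixel_spacing)
    fv <- extract_all(sub_q, params = params, region = "block")
    pos <- (b$col - 1L) * nbr + b$row
    store[paste(fv$family, fv$feature), pos] <- fv$value
    valid[b$row, b$col] <- TRUE
  }
  out <- lapply(features, function(key) {
    row_i <- match(key, catalog_keys)
    texture_map(catalog$feature[row_i], catalog$family[row_i],
                matrix(store[key, ], nbr, nbc), valid, grid$block_mm)
  })
  names(out) <- features
  out
}

#' Median summary of a texture map
#'
#' Median over valid blocks only (the even-count median is the mean of the
#' central pair, as with [stats::median()]).
#'
#' @param m A [texture_map()].
#' @return A single numeric value.
#' @export
map_median <- function(m) {
  stopifnot(inherits(m, "texture_map"))
  v <- m$values[m$valid & is.finite(m$values)]
  if (length(v) == 0L) stop("texture map has no valid blocks", call. = FALSE)
  stats::median(v)
}

#' Median summaries for a list of texture maps
#'
#' @param maps A named list of [texture_map()]s from
#'   [compute_texture_map()].
#' @return A tibble with columns `family`, `feature`, `median`,
#'   `n_valid_blocks`.
#' @export
map_medians <- function(maps) {
  purrr::map_dfr(maps, function(m) {
    tibble::tibble(family = m$family, feature = m$feature,
                   median = map_median(m),
                   n_valid_blocks = sum(m$valid))
  })
}
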
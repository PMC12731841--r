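# Second-pass (texture-derivative) analysis: texture matrices computed on
# first-pass texture maps, treating each block as one pixel. Features are
# named "first-pass feature<en dash>second-pass feature", e.g.
# "Cluster Prominence-Sum Entropy" (with U+2013 as the joiner).

#' Requantize a texture map into gray levels
#'
#' Valid blocks are quantized into `Ng2` equal-width bins spanning the
#' valid-value range; invalid blocks fall outside the ROI of the derived
#' image. A constant map maps every valid block to level 1.
#'
#' @param m A [texture_map()].
#' @param Ng2 Second-pass gray-level count (default 16; maps hold few
#'   samples, so a coarser scale than the first pass is used).
#' @return A [quantized_image()] over the block grid (unit spacing).
#' @export
requantize_map <- function(m, Ng2 = 16L) {
  stopifnot(inherits(m, "texture_map"))
  if (Ng2 < 2L) stop("`Ng2` must be at least 2", call. = FALSE)
  ok <- m$valid & is.finite(m$values)
  if (!any(ok)) stop("texture map has no valid blocks", call. = FALSE)
  Ng2 <- as.integer(Ng2)
  vals <- m$values[ok]
  rng <- range(vals)
  lv <- matrix(0L, nrow(m$values), ncol(m$values))
  if (rng[2L] > rng[1L]) {
    edges <- seq(rng[1L], rng[2L], length.out = Ng2 + 1L)
    lv[ok] <- pmin.int(
      pmax.int(findInterval(vals, edges, rightmost.closed = TRUE), 1L), Ng2)
  } else {
    edges <- rng[1L] + seq(-0.5, 0.5, length.out = Ng2 + 1L)
    lv[ok] <- 1L
  }
  quantized_image(lv, Ng2, edges, 1)
}

#' Default second-pass feature set
#'
#' Thirteen GLCM and GLDM features applied to every first-pass map. The
#' set covers the pair- and dependence-based summaries reported for
#' second-pass analysis (sum entropy, information measure of correlation
#' 2, cluster prominence, high/low gray-level emphasis, dependence
#' variance) plus the standard homogeneity/disorder summaries of those two
#' families.
#'
#' @return A tibble with columns `family`, `feature` (13 rows).
#' @export
second_pass_features <- function() {
  tibble::tibble(
    family = c(rep("GLCM", 9L), rep("GLDM", 4L)),
    feature = c(
      "Contrast", "Correlation", "Cluster Prominence", "Sum Entropy",
      "Difference Entropy", "Informational Measure of Correlation 2",
      "Inverse Difference Normalized", "Inverse Difference Moment Normalized",
      "Joint Energy",
      "High Gray Level Emphasis", "Low Gray Level Emphasis",
      "Dependence Variance", "Small Dependence Low Gray Level Emphasis"
    )
  )
}

#' Texture-derivative features from first-pass maps
#'
#' For each map: requantize with [requantize_map()], then run the GLCM and
#' GLDM extractors on the block grid treated as an image (one block = one
#' pixel, unit spacing). Maps with fewer than 2 x 2 valid blocks cannot
#' support pair-based matrices; their entries are returned as `NA` and
#' flagged, never dropped, so the vector length is always
#' `length(maps) * nrow(second_pass)`.
#'
#' @param maps A named list of [texture_map()]s from
#'   [compute_texture_map()].
#' @param second_pass Tibble of second-pass features (columns `family`,
#'   `feature`); default [second_pass_features()].
#' @param Ng2 Second-pass gray-level count (default 16).
#' @param params A [texture_params()] for the second-pass matrices.
#' @return A tibble with columns `map_family`, `map_feature`,
#'   `second_family`, `second_feature`, `name`
#'   (`"map feature–second feature"`), `value`, `n_valid_blocks`,
#'   `computed`.
#' @export
derivative_features <- function(maps, second_pass = second_pass_features(),
                                Ng2 = 16L, params = texture_params()) {
  stopifnot(is.list(maps), all(vapply(maps, inherits, logical(1),
                                      "texture_map")))
  sp_keys <- paste(second_pass$family, second_pass$feature)
  purrr::map_dfr(maps, function(m) {
    ok <- m$valid & is.finite(m$values)
    n_ok <- sum(ok)
    # pair-based second-pass matrices need a 2 x 2 patch of valid blocks
    has_2x2 <- n_ok >= 4L && {
      both <- ok[-nrow(ok), -ncol(ok), drop = FALSE] &
        ok[-1L, -ncol(ok), drop = FALSE] &
        ok[-nrow(ok), -1L, drop = FALSE] & ok[-1L, -1L, drop = FALSE]
      any(both)
    }
    base <- tibble::tibble(
      map_family = m$family, map_feature = m$feature,
      second_family = second_pass$family,
      second_feature = second_pass$feature,
      name = paste0(m$feature, "\u2013", second_pass$feature),
      n_valid_blocks = n_ok)
    if (!has_2x2) {
      warning(sprintf("map '%s %s' has no 2x2 valid patch; emitting NA",
                      m$family, m$feature), call. = FALSE)
      return(tibble::tibble(base, value = NA_real_, computed = FALSE))
    }
    q2 <- requantize_map(m, Ng2 = Ng2)
    fv <- dplyr::bind_rows(
      glcm_features(compute_glcm(q2, distance = params$glcm_distance,
                                 symmetric = params$glcm_symmetric)),
      gldm_features(compute_gldm(q2, alpha = params$gldm_alpha,
                                 distance = params$gldm_distance))
    )
    vals <- fv$value[match(sp_keys, paste(fv$family, fv$feature))]
    tibble::tibble(base, value = vals, computed = TRUE)
  })
}
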
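# Gray-level dependence matrix (GLDM) and its 14 features.
#
# For each in-ROI pixel, its dependence is the number of in-ROI neighbours
# within the Chebyshev distance whose gray level differs from the centre by
# at most alpha (the centre itself is not counted). The matrix counts
# pixels by (gray level, dependence).

#' Compute the gray-level dependence matrix
#'
#' @param q A [quantized_image()].
#' @param roi Optional [roi_mask()]; defaults to the non-zero levels of `q`.
#' @param alpha Dependence tolerance on the level difference (default 0).
#' @param distance Chebyshev neighbourhood radius in pixels (default 1).
#' @return An object of class `gldm`: `counts` is `Ng x (Dmax + 1)` with
#'   columns labelled by dependence 0..Dmax (neighbours only).
#' @export
compute_gldm <- function(q, roi = NULL, alpha = 0, distance = 1L) {
  stopifnot(inherits(q, "quantized_image"))
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  lv <- q$levels
  if (!is.null(roi)) {
    m <- as_mask_matrix(roi, dim(lv))
    lv[!m] <- 0L
  }
  if (!any(lv > 0L)) stop("ROI is empty", call. = FALSE)
  nr <- nrow(lv); nc <- ncol(lv)
  dep <- matrix(0L, nr, nc)
  d <- as.integer(distance)
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0L && dc == 0L) next
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    a <- lv[r1:r2, c1:c2, drop = FALSE]
    b <- lv[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
    ok <- a > 0L & b > 0L & abs(a - b) <= alpha
    dep[r1:r2, c1:c2] <- dep[r1:r2, c1:c2] + ok
  }
  inroi <- lv > 0L
  dmax <- max(dep[inroi])
  Ng <- q$Ng
  idx <- (lv[inroi] - 1L) * (dmax + 1L) + dep[inroi] + 1L
  counts <- matrix(tabulate(idx, nbins = Ng * (dmax + 1L)),
                   Ng, dmax + 1L, byrow = TRUE)
  structure(
    list(counts = counts, alpha = alpha, distance = d, Ng = Ng,
         Np = sum(inroi)),
    class = "gldm"
  )
}

#' GLDM features (14)
#'
#' Dependence size enters the feature formulas as the neighbour count plus
#' one (i.e. including the centre pixel), which keeps small-dependence
#' emphases finite for isolated pixels; dependence variance and entropy are
#' unaffected by this shift-invariant convention.
#'
#' @param m A `gldm` from [compute_gldm()].
#' @return A tibble with columns `family`, `feature`, `value` (14 rows).
#' @export
gldm_features <- function(m) {
  stopifnot(inherits(m, "gldm"))
  C <- m$counts
  N <- sum(C)
  if (N < 1) stop("GLDM is empty", call. = FALSE)
  Ng <- nrow(C)
  i <- seq_len(Ng)
  j <- seq_len(ncol(C))          # dependence size = neighbours + 1
  gi <- rowSums(C)
  dj <- colSums(C)
  p <- C / N
  mu_i <- sum(rowSums(p) * i)
  mu_j <- sum(colSums(p) * j)
  ent <- function(pp) { pp <- pp[pp > 0]; -sum(pp * log2(pp)) }

  vals <- c(
    "Small Dependence Emphasis" = sum(t(t(C) / j^2)) / N,
    "Large Dependence Emphasis" = sum(t(t(C) * j^2)) / N,
    "Gray Level Non-Uniformity" = sum(gi^2) / N,
    "Dependence Non-Uniformity" = sum(dj^2) / N,
    "Dependence Non-Uniformity Normalized" = sum(dj^2) / N^2,
    "Gray Level Variance"       = sum(rowSums(p) * (i - mu_i)^2),
    "Dependence Variance"       = sum(colSums(p) * (j - mu_j)^2),
    "Dependence Entropy"        = ent(p),
    "Low Gray Level Emphasis"   = sum(C / i^2) / N,
    "High Gray Level Emphasis"  = sum(C * i^2) / N,
    "Small Dependence Low Gray Level Emphasis"  = sum(t(t(C / i^2) / j^2)) / N,
    "Small Dependence High Gray Level Emphasis" = sum(t(t(C * i^2) / j^2)) / N,
    "Large Dependence Low Gray Level Emphasis"  = sum(t(t(C / i^2) * j^2)) / N,
    "Large Dependence High Gray Level Emphasis" = sum(t(t(C * i^2) * j^2)) / N
  )
  tibble::tibble(family = "GLDM", feature = names(vals),
                 value = unname(vals))
}
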
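# Neighbourhood gray-tone difference matrix (NGTDM) and its 5 features.
#
# For each in-ROI pixel with at least one in-ROI neighbour among its eight
# surrounding pixels, the absolute difference between its level and the
# mean level of those neighbours is accumulated per gray level.

#' Compute the neighbourhood gray-tone difference matrix
#'
#' Border or masked neighbourhoods use only the in-ROI neighbours that
#' exist; pixels with no in-ROI neighbour are skipped.
#'
#' @param q A [quantized_image()].
#' @param roi Optional [roi_mask()]; defaults to the non-zero levels of `q`.
#' @param distance Chebyshev neighbourhood radius in pixels (default 1,
#'   i.e. the eight surrounding pixels).
#' @return An object of class `ngtdm` with per-level sums `s`, pixel
#'   counts `n` and probabilities `p` (vectors of length `Ng`).
#' @export
compute_ngtdm <- function(q, roi = NULL, distance = 1L) {
  stopifnot(inherits(q, "quantized_image"))
  lv <- q$levels
  if (!is.null(roi)) {
    m <- as_mask_matrix(roi, dim(lv))
    lv[!m] <- 0L
  }
  if (!any(lv > 0L)) stop("ROI is empty", call. = FALSE)
  nr <- nrow(lv); nc <- ncol(lv)
  nb_sum <- matrix(0, nr, nc)
  nb_cnt <- matrix(0L, nr, nc)
  d <- as.integer(distance)
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0L && dc == 0L) next
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    b <- lv[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
    ok <- b > 0L
    nb_sum[r1:r2, c1:c2] <- nb_sum[r1:r2, c1:c2] + b * ok
    nb_cnt[r1:r2, c1:c2] <- nb_cnt[r1:r2, c1:c2] + ok
  }
  use <- lv > 0L & nb_cnt > 0L
  if (!any(use)) {
    stop("no ROI pixel has an in-ROI neighbour", call. = FALSE)
  }
  Ng <- q$Ng
  diff <- abs(lv[use] - nb_sum[use] / nb_cnt[use])
  lev <- lv[use]
  s <- vapply(seq_len(Ng), function(k) sum(diff[lev == k]), numeric(1))
  n <- tabulate(lev, nbins = Ng)
  structure(
    list(s = s, n = n, p = n / sum(n), Ng = Ng, Nvp = sum(n)),
    class = "ngtdm"
  )
}

#' NGTDM features (5): coarseness, contrast, busyness, complexity, strength
#'
#' Degenerate denominators are handled explicitly: a zero coarseness
#' denominator (perfectly flat image) returns the documented cap `1e6`;
#' zero busyness or strength denominators return 0.
#'
#' @param m An `ngtdm` from [compute_ngtdm()].
#' @return A tibble with columns `family`, `feature`, `value` (5 rows).
#' @export
ngtdm_features <- function(m) {
  stopifnot(inherits(m, "ngtdm"))
  if (m$Nvp < 1L) stop("NGTDM is empty", call. = FALSE)
  p <- m$p; s <- m$s; n <- m$n; Ng <- m$Ng
  N <- m$Nvp
  i <- seq_len(Ng)
  nz <- which(p > 0)
  Ngp <- length(nz)

  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6

  contrast <- if (Ngp > 1L) {
    pij2 <- outer(p[nz], p[nz]) * outer(i[nz], i[nz], function(a, b) (a - b)^2)
    sum(pij2) / (Ngp * (Ngp - 1L)) * sum(s) / N
  } else 0

  busy_den <- sum(abs(outer(i[nz] * p[nz], i[nz] * p[nz], "-")))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0

  complexity <- if (Ngp > 0L) {
    num <- outer(i[nz], i[nz], function(a, b) abs(a - b)) *
      outer(p[nz] * s[nz], p[nz] * s[nz], "+") /
      outer(p[nz], p[nz], "+")
    sum(num) / N
  } else 0

  str_num <- sum(outer(p[nz], p[nz], "+") *
                   outer(i[nz], i[nz], function(a, b) (a - b)^2))
  strength <- if (sum(s) > 0) str_num / sum(s) else 0

  vals <- c(
    "Coarseness" = coarseness,
    "Contrast"   = contrast,
    "Busyness"   = busyness,
    "Complexity" = complexity,
    "Strength"   = strength
  )
  tibble::tibble(family = "NGTDM", feature = names(vals),
                 value = unname(vals))
}
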
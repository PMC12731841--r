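# Gray-level co-occurrence matrix (GLCM) and its 24 features.
#
# The GLCM counts, for a fixed pixel offset, how often a pixel of gray
# level i is paired with one of level j; both pixels must lie inside the
# ROI. Features follow the canonical (IBSI-aligned) definitions and are
# averaged over the four 2D directions.

# offsets for the four 2D directions: 0, 45, 90, 135 degrees
glcm_default_angles <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

# count co-occurring level pairs at a single (dr, dc) offset
glcm_count_offset <- function(lv, Ng, dr, dc) {
  nr <- nrow(lv); nc <- ncol(lv)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  counts <- matrix(0, Ng, Ng)
  if (r1 > r2 || c1 > c2) return(counts)
  a <- lv[r1:r2, c1:c2, drop = FALSE]
  b <- lv[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(counts)
  idx <- (a[ok] - 1L) * Ng + b[ok]
  counts + matrix(tabulate(idx, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
}

#' Compute gray-level co-occurrence matrices
#'
#' One count matrix per direction at the given pixel distance; both members
#' of a pair must be inside the ROI. In symmetric mode (the default) each
#' matrix is accumulated together with its transpose, so pairs are counted
#' in both directions.
#'
#' @param q A [quantized_image()].
#' @param roi Optional [roi_mask()]; defaults to the non-zero levels of `q`.
#' @param distance Pixel distance between pair members (default 1).
#' @param angles List of `c(dr, dc)` unit offsets; default the four 2D
#'   directions (0, 45, 90, 135 degrees).
#' @param symmetric Accumulate each offset with its opposite (default TRUE).
#' @return An object of class `glcm` holding per-angle count and
#'   probability matrices.
#' @export
compute_glcm <- function(q, roi = NULL, distance = 1L,
                         angles = glcm_default_angles(), symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_image"))
  if (length(angles) == 0L) stop("angle set must be non-empty", call. = FALSE)
  lv <- q$levels
  if (!is.null(roi)) {
    m <- as_mask_matrix(roi, dim(lv))
    lv[!m] <- 0L
  }
  if (!any(lv > 0L)) stop("ROI is empty", call. = FALSE)
  Ng <- q$Ng
  counts <- lapply(angles, function(a) {
    cnt <- glcm_count_offset(lv, Ng, a[1L] * distance, a[2L] * distance)
    if (symmetric) cnt <- cnt + t(cnt)
    cnt
  })
  probs <- lapply(counts, function(cnt) {
    s <- sum(cnt)
    if (s > 0) cnt / s else cnt
  })
  structure(
    list(counts = counts, probabilities = probs, angles = angles,
         distance = distance, symmetric = symmetric, Ng = Ng),
    class = "glcm"
  )
}

# features of one normalized GLCM
glcm_features_single <- function(P, Ng) {
  eps <- .Machine$double.eps
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(px * seq_len(Ng)); muy <- sum(py * seq_len(Ng))
  sdx <- sqrt(sum(px * (seq_len(Ng) - mux)^2))
  sdy <- sqrt(sum(py * (seq_len(Ng) - muy)^2))

  # diagonal (difference) and cross-diagonal (sum) marginals
  k_diff <- 0:(Ng - 1L)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2L * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))

  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  da <- sum(k_diff * p_diff)
  HX <- ent2(px); HY <- ent2(py); HXY <- ent2(P)
  pxy <- outer(px, py)
  HXY1 <- -sum(P[P > 0 & pxy > 0] * log2(pxy[P > 0 & pxy > 0]))
  HXY2 <- ent2(pxy)

  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))

  correlation <- if (sdx > eps && sdy > eps) {
    (sum(P * i * j) - mux * muy) / (sdx * sdy)
  } else 1  # degenerate marginal: perfectly predictable

  # maximal correlation coefficient: sqrt of 2nd-largest eigenvalue of
  # Q(a,b) = sum_k P(a,k) P(b,k) / (px(a) py(k))
  keep <- px > 0 & py > 0
  mcc <- if (sum(keep) < 2L) 1 else {
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- (Pk / pxk) %*% (t(Pk) / pyk)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(ev[2L], 1)))
  }

  c(
    "Autocorrelation"                    = sum(P * i * j),
    "Joint Average"                      = mux,
    "Cluster Prominence"                 = sum(P * (i + j - mux - muy)^4),
    "Cluster Shade"                      = sum(P * (i + j - mux - muy)^3),
    "Cluster Tendency"                   = sum(P * (i + j - mux - muy)^2),
    "Contrast"                           = sum(P * (i - j)^2),
    "Correlation"                        = correlation,
    "Difference Average"                 = da,
    "Difference Entropy"                 = ent2(p_diff),
    "Difference Variance"                = sum(p_diff * (k_diff - da)^2),
    "Joint Energy"                       = sum(P^2),
    "Joint Entropy"                      = HXY,
    "Informational Measure of Correlation 1" = imc1,
    "Informational Measure of Correlation 2" = imc2,
    "Inverse Difference"                 = sum(P / (1 + abs(i - j))),
    "Inverse Difference Normalized"      = sum(P / (1 + abs(i - j) / Ng)),
    "Inverse Difference Moment"          = sum(P / (1 + (i - j)^2)),
    "Inverse Difference Moment Normalized" = sum(P / (1 + (i - j)^2 / Ng^2)),
    "Inverse Variance"                   = sum(P[i != j] / (i - j)[i != j]^2),
    "Maximum Probability"                = max(P),
    "Maximal Correlation Coefficient"    = mcc,
    "Sum Average"                        = sum(k_sum * p_sum),
    "Sum Entropy"                        = ent2(p_sum),
    "Sum of Squares"                     = sum(P * (i - mux)^2)
  )
}

#' GLCM features (24), averaged over directions
#'
#' @param m A `glcm` from [compute_glcm()].
#' @return A tibble with columns `family`, `feature`, `value` (24 rows).
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  use <- Filter(function(P) sum(P) > 0, m$probabilities)
  if (length(use) == 0L) stop("GLCM has no counted pairs", call. = FALSE)
  for (P in use) {
    if (abs(sum(P) - 1) > 1e-9) {
      stop("internal error: GLCM probabilities not normalized", call. = FALSE)
    }
  }
  per_angle <- vapply(use, glcm_features_single, numeric(24L), Ng = m$Ng)
  vals <- rowMeans(per_angle)
  tibble::tibble(family = "GLCM", feature = names(vals),
                 value = unname(vals))
}
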
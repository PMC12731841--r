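# Gray-level size zone matrix (GLSZM) and its 16 features.
#
# A zone is a maximal 8-connected set of in-ROI pixels sharing one gray
# level; the matrix counts zones by (gray level, zone size). Sensitive to
# the large homogeneous regions that necrosis produces.

#' Compute the gray-level size zone matrix
#'
#' Zones are found by 8-connected labelling restricted to the ROI.
#'
#' @param q A [quantized_image()].
#' @param roi Optional [roi_mask()]; defaults to the non-zero levels of `q`.
#' @return An object of class `glszm` with the `counts` matrix
#'   (`Ng x max zone size`), zone count `Nz` and in-ROI pixel count `Np`.
#' @export
compute_glszm <- function(q, roi = NULL) {
  stopifnot(inherits(q, "quantized_image"))
  lv <- q$levels
  if (!is.null(roi)) {
    m <- as_mask_matrix(roi, dim(lv))
    lv[!m] <- 0L
  }
  idx <- which(lv > 0L)
  if (length(idx) == 0L) stop("ROI is empty", call. = FALSE)
  zones <- label_zones(lv)
  Ng <- q$Ng
  smax <- max(zones$size)
  counts <- matrix(0, Ng, smax)
  for (k in seq_along(zones$size)) {
    counts[zones$level[k], zones$size[k]] <-
      counts[zones$level[k], zones$size[k]] + 1
  }
  structure(
    list(counts = counts, Nz = length(zones$size), Np = length(idx),
         Ng = Ng, connectivity = "8-connected"),
    class = "glszm"
  )
}

# label 8-connected constant-level zones; returns per-zone level and size
label_zones <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  inroi <- lv > 0L
  idx <- which(inroi)
  # edges to 4 forward neighbours (E, S, SE, SW) when levels match
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    dr <- o[1L]; dc <- o[2L]
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    a <- lv[r1:r2, c1:c2, drop = FALSE]
    b <- lv[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
    ok <- a > 0L & a == b
    if (!any(ok)) next
    # linear indices in the full matrix
    rr <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L)
    cc <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
    ia <- (cc[ok] - 1L) * nr + rr[ok]
    ib <- (cc[ok] + dc - 1L) * nr + rr[ok] + dr
    from <- c(from, ia); to <- c(to, ib)
  }
  # compress to in-ROI vertex ids
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_graph(c(rbind(vid[from], vid[to])), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)
  size <- as.integer(comp$csize)
  level <- integer(comp$no)
  level[comp$membership] <- lv[idx]  # every member shares the zone level
  list(level = level, size = size)
}

#' GLSZM features (16)
#'
#' @param m A `glszm` from [compute_glszm()].
#' @return A tibble with columns `family`, `feature`, `value` (16 rows).
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "glszm"))
  if (m$Nz < 1L) stop("GLSZM has no zones", call. = FALSE)
  C <- m$counts
  Nz <- m$Nz; Np <- m$Np
  Ng <- nrow(C); Smax <- ncol(C)
  i <- seq_len(Ng); s <- seq_len(Smax)
  gi <- rowSums(C)           # zones per gray level
  ss <- colSums(C)           # zones per size
  p <- C / Nz
  mu_i <- sum(rowSums(p) * i)
  mu_s <- sum(colSums(p) * s)
  ent <- function(pp) { pp <- pp[pp > 0]; -sum(pp * log2(pp)) }

  vals <- c(
    "Small Area Emphasis"        = sum(t(C) / s^2) / Nz,
    "Large Area Emphasis"        = sum(t(C) * s^2) / Nz,
    "Gray Level Non-Uniformity"  = sum(gi^2) / Nz,
    "Gray Level Non-Uniformity Normalized" = sum(gi^2) / Nz^2,
    "Size Zone Non-Uniformity"   = sum(ss^2) / Nz,
    "Size Zone Non-Uniformity Normalized" = sum(ss^2) / Nz^2,
    "Zone Percentage"            = Nz / Np,
    "Gray Level Variance"        = sum(rowSums(p) * (i - mu_i)^2),
    "Zone Variance"              = sum(colSums(p) * (s - mu_s)^2),
    "Zone Entropy"               = ent(p),
    "Low Gray Level Zone Emphasis"  = sum(C / i^2) / Nz,
    "High Gray Level Zone Emphasis" = sum(C * i^2) / Nz,
    "Small Area Low Gray Level Emphasis"  = sum(t(t(C / i^2) / s^2)) / Nz,
    "Small Area High Gray Level Emphasis" = sum(t(t(C * i^2) / s^2)) / Nz,
    "Large Area Low Gray Level Emphasis"  = sum(t(t(C / i^2) * s^2)) / Nz,
    "Large Area High Gray Level Emphasis" = sum(t(t(C * i^2) * s^2)) / Nz
  )
  tibble::tibble(family = "GLSZM", feature = names(vals),
                 value = unname(vals))
}
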
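# Semi-quantitative DCE-MRI analysis and perfusion-targeted treatment-cell
# exclusion masks: percentage enhancement, baseline-subtracted initial AUC
# over the first two minutes, muscle normalisation, transverse maximum
# intensity projection, tertile exclusion, and the 1.2 mm treatment-cell
# grid over an 18 mm analysis region.

#' DCE-MRI series container
#'
#' @param signal 4D numeric array `(x, y, z, t)`.
#' @param times Acquisition time of each frame in seconds, strictly
#'   increasing.
#' @param baseline_frames Indices of pre-contrast frames (>= 1).
#' @param voxel_spacing Voxel spacing in millimetres (isotropic in-plane).
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(signal, times, baseline_frames, voxel_spacing = 1) {
  if (length(dim(signal)) != 4L) {
    stop("`signal` must be a 4D (x, y, z, t) array", call. = FALSE)
  }
  if (length(times) != dim(signal)[4L]) {
    stop("`times` must have one entry per frame", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (length(baseline_frames) < 1L ||
      any(baseline_frames < 1L | baseline_frames > length(times))) {
    stop("`baseline_frames` must index at least one frame", call. = FALSE)
  }
  structure(
    list(signal = signal, times = as.numeric(times),
         baseline_frames = as.integer(baseline_frames),
         voxel_spacing = voxel_spacing),
    class = "dce_series"
  )
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<dce_series> %d x %d x %d voxels, %d frames (%.0f-%.0f s), %d baseline\n",
    d[1L], d[2L], d[3L], d[4L], min(x$times), max(x$times),
    length(x$baseline_frames)))
  invisible(x)
}

baseline_map <- function(series) {
  bl <- series$signal[, , , series$baseline_frames, drop = FALSE]
  apply(bl, 1:3, mean)
}

#' Percentage signal enhancement curve
#'
#' `100 * (S(t) - S0) / S0` with `S0` the mean over the baseline frames.
#' With an ROI, the curve is computed on the ROI-mean signal.
#'
#' @param series A [dce_series()].
#' @param roi Optional 3D logical array selecting voxels; default the whole
#'   volume.
#' @return A tibble with columns `time` (s) and `enhancement_pct`.
#' @export
percent_enhancement <- function(series, roi = NULL) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$signal)
  if (is.null(roi)) roi <- array(TRUE, d[1:3])
  if (!identical(dim(roi), d[1:3])) {
    stop("ROI shape does not match the series", call. = FALSE)
  }
  nt <- d[4L]
  s_t <- vapply(seq_len(nt), function(t) {
    mean(series$signal[, , , t][roi])
  }, numeric(1))
  s0 <- mean(s_t[series$baseline_frames])
  if (!is.finite(s0) || s0 <= 0) {
    stop("baseline signal must be positive", call. = FALSE)
  }
  tibble::tibble(time = series$times,
                 enhancement_pct = 100 * (s_t - s0) / s0)
}

#' Initial area under the enhancement curve
#'
#' Per-voxel trapezoidal integral of the baseline-subtracted signal over
#' `[injection_time, injection_time + window]` (default the first two
#' minutes after injection). If the window extends past the last frame the
#' integral runs to the last frame with a warning.
#'
#' @param series A [dce_series()].
#' @param injection_time Injection time in seconds; default the time of
#'   the first frame after the baseline set.
#' @param window Integration window in seconds (default 120).
#' @return An object of class `auc_map` with the 3D `auc` array
#'   (signal x seconds); `auc_norm` is filled by [normalize_auc()].
#' @export
auc_initial <- function(series, injection_time = NULL, window = 120) {
  stopifnot(inherits(series, "dce_series"))
  times <- series$times
  if (is.null(injection_time)) {
    after <- setdiff(seq_along(times), series$baseline_frames)
    if (length(after) == 0L) stop("no post-baseline frames", call. = FALSE)
    injection_time <- times[min(after)]
  }
  t_end <- injection_time + window
  if (t_end > max(times)) {
    warning("integration window extends past the last frame; truncating")
    t_end <- max(times)
  }
  keep <- which(times >= injection_time & times <= t_end)
  if (length(keep) < 2L) {
    stop("need at least two frames inside the integration window",
         call. = FALSE)
  }
  s0 <- baseline_map(series)
  tk <- times[keep]
  dt <- diff(tk)
  d <- dim(series$signal)
  auc <- array(0, d[1:3])
  for (k in seq_len(length(keep) - 1L)) {
    e1 <- series$signal[, , , keep[k]] - s0
    e2 <- series$signal[, , , keep[k + 1L]] - s0
    auc <- auc + (e1 + e2) / 2 * dt[k]
  }
  structure(
    list(auc = auc, auc_norm = NULL, muscle_auc = NA_real_,
         injection_time = injection_time, window = window),
    class = "auc_map"
  )
}

#' Normalise an AUC map by a muscle reference
#'
#' Divides the per-voxel AUC by the mean AUC inside a muscle ROI, removing
#' scan- and injection-dependent scaling.
#'
#' @param auc_map An `auc_map` from [auc_initial()].
#' @param muscle_roi 3D logical array selecting the muscle reference.
#' @return The `auc_map` with `auc_norm` and `muscle_auc` filled.
#' @export
normalize_auc <- function(auc_map, muscle_roi) {
  stopifnot(inherits(auc_map, "auc_map"))
  if (!identical(dim(muscle_roi), dim(auc_map$auc))) {
    stop("muscle ROI shape does not match the AUC map", call. = FALSE)
  }
  mu <- mean(auc_map$auc[muscle_roi])
  if (!is.finite(mu) || mu <= 0) {
    stop("muscle AUC must be positive", call. = FALSE)
  }
  auc_map$auc_norm <- auc_map$auc / mu
  auc_map$muscle_auc <- mu
  auc_map
}

#' Maximum intensity projection across transverse slices
#'
#' @param auc_map An `auc_map`; projects `auc_norm` when available,
#'   otherwise `auc`.
#' @return A 2D matrix of per-(x, y) maxima over z (class `mip_image`).
#' @export
mip_transverse <- function(auc_map) {
  stopifnot(inherits(auc_map, "auc_map"))
  vol <- if (!is.null(auc_map$auc_norm)) auc_map$auc_norm else auc_map$auc
  out <- apply(vol, 1:2, max)
  class(out) <- c("mip_image", class(out))
  out
}

#' Tertile exclusion mask from a MIP
#'
#' Targets low- or high-perfusion tumour: `low_target` excludes the third
#' of tumour MIP pixels with the highest values (treating the
#' lowest-perfusion two thirds); `high_target` excludes the lowest third.
#' `ceiling(n/3)` pixels are excluded so `floor(2n/3)` remain. Ties are
#' broken by stable (value, pixel index) ordering with a warning when the
#' boundary is tied.
#'
#' @param mip A 2D MIP matrix (see [mip_transverse()]).
#' @param tumor_mask 2D logical matrix of the tumour footprint (a 3D mask
#'   is collapsed by any-z).
#' @param mode `"low_target"` or `"high_target"`.
#' @return A list: `excluded` (2D logical), `kept` (2D logical),
#'   `n_tumor`, `n_excluded`, `n_kept`, `treated_pct`
#'   (`floor(100 * kept / n)`), `mode`.
#' @export
exclusion_mask <- function(mip, tumor_mask,
                           mode = c("low_target", "high_target")) {
  mode <- match.arg(mode)
  if (length(dim(tumor_mask)) == 3L) {
    tumor_mask <- apply(tumor_mask, 1:2, any)
  }
  stopifnot(identical(dim(mip)[1:2], dim(tumor_mask)[1:2]))
  idx <- which(tumor_mask)
  n <- length(idx)
  if (n < 3L) stop("need at least three tumour pixels", call. = FALSE)
  vals <- mip[idx]
  k_excl <- ceiling(n / 3)
  ord <- order(vals, idx)              # stable: value then pixel index
  excl_idx <- if (mode == "low_target") {
    idx[ord[(n - k_excl + 1L):n]]      # drop the highest-perfusion third
  } else {
    idx[ord[seq_len(k_excl)]]          # drop the lowest-perfusion third
  }
  cut_val <- if (mode == "low_target") sort(vals)[n - k_excl + 1L]
             else sort(vals)[k_excl]
  if (sum(vals == cut_val) > 1L) {
    warning("tied MIP values at the tertile boundary; ",
            "stable pixel-order tie-break applied")
  }
  excluded <- matrix(FALSE, nrow(tumor_mask), ncol(tumor_mask))
  excluded[excl_idx] <- TRUE
  kept <- tumor_mask & !excluded
  list(excluded = excluded, kept = kept, n_tumor = n,
       n_excluded = k_excl, n_kept = n - k_excl,
       treated_pct = floor(100 * (n - k_excl) / n), mode = mode)
}

#' Build the treatment-cell grid
#'
#' A square lattice of `cell_mm` cells covering the `region_diameter`
#' analysis disc (18 mm diameter and 1.2 mm cells give 15 x 15 cells);
#' cells fully outside the disc are dropped. The grid is centred on the
#' analysis region.
#'
#' @param region_diameter Analysis region diameter in mm (default 18).
#' @param cell_mm Cell side in mm (default 1.2).
#' @param voxel_spacing In-plane voxel spacing in mm.
#' @param dims 2D image dimensions `(nx, ny)` the grid overlays; default
#'   exactly covers the region.
#' @return An object of class `cell_grid`: tibble `cells` (`cell`, `row`,
#'   `col`, voxel window, `in_region`) plus metadata.
#' @export
build_cell_grid <- function(region_diameter = 18, cell_mm = 1.2,
                            voxel_spacing = 1,
                            dims = rep(ceiling(region_diameter /
                                                 voxel_spacing), 2L)) {
  if (region_diameter <= 0 || cell_mm <= 0 || voxel_spacing <= 0) {
    stop("sizes must be positive", call. = FALSE)
  }
  if (cell_mm > region_diameter) {
    stop("`cell_mm` cannot exceed `region_diameter`", call. = FALSE)
  }
  n_cells <- as.integer(round(region_diameter / cell_mm))
  cell_px <- cell_mm / voxel_spacing
  # grid centred on the region centre
  cx <- dims[1L] / 2; cy <- dims[2L] / 2
  x0 <- cx - n_cells * cell_px / 2
  y0 <- cy - n_cells * cell_px / 2
  grid <- expand.grid(col = seq_len(n_cells), row = seq_len(n_cells))
  r0 <- pmax(1L, as.integer(floor(x0 + (grid$row - 1) * cell_px)) + 1L)
  r1 <- pmin(dims[1L], as.integer(floor(x0 + grid$row * cell_px)))
  c0 <- pmax(1L, as.integer(floor(y0 + (grid$col - 1) * cell_px)) + 1L)
  c1 <- pmin(dims[2L], as.integer(floor(y0 + grid$col * cell_px)))
  # cell-centre distance from the region centre, in mm
  ccx <- x0 + (grid$row - 0.5) * cell_px
  ccy <- y0 + (grid$col - 0.5) * cell_px
  dist_mm <- sqrt((ccx - cx)^2 + (ccy - cy)^2) * voxel_spacing
  # drop cells whose nearest point lies outside the disc
  half_diag <- cell_mm * sqrt(2) / 2
  in_region <- dist_mm - half_diag <= region_diameter / 2 & r0 <= r1 &
    c0 <= c1
  cells <- tibble::tibble(
    cell = seq_len(nrow(grid)), row = as.integer(grid$row),
    col = as.integer(grid$col), r0 = r0, r1 = r1, c0 = c0, c1 = c1,
    in_region = in_region)
  structure(
    list(cells = cells, n_cells = n_cells, cell_mm = cell_mm,
         region_diameter = region_diameter, voxel_spacing = voxel_spacing),
    class = "cell_grid"
  )
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf(
    "<cell_grid> %d x %d cells of %g mm over a %g mm region (%d in region)\n",
    x$n_cells, x$n_cells, x$cell_mm, x$region_diameter,
    sum(x$cells$in_region)))
  invisible(x)
}

#' Apply a voxel exclusion mask to the treatment-cell grid
#'
#' A cell is excluded from sonication when it contains at least one
#' excluded voxel (the any-voxel rule), so the cell-level treated volume
#' never exceeds the voxel-level one.
#'
#' @param grid A [build_cell_grid()] result.
#' @param excl An [exclusion_mask()] result.
#' @return The grid's `cells` tibble with `n_voxels`, `n_excluded_voxels`
#'   and `kept` columns.
#' @export
apply_exclusion_to_cells <- function(grid, excl) {
  stopifnot(inherits(grid, "cell_grid"))
  cells <- grid$cells
  n_vox <- integer(nrow(cells)); n_exc <- integer(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    b <- cells[k, ]
    if (!b$in_region || b$r0 > b$r1 || b$c0 > b$c1) next
    tum <- excl$kept[b$r0:b$r1, b$c0:b$c1] |
      excl$excluded[b$r0:b$r1, b$c0:b$c1]
    n_vox[k] <- sum(tum)
    n_exc[k] <- sum(excl$excluded[b$r0:b$r1, b$c0:b$c1])
  }
  dplyr::mutate(cells, n_voxels = n_vox, n_excluded_voxels = n_exc,
                kept = in_region & n_vox > 0L & n_exc == 0L)
}
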
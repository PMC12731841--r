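# Synthetic phantoms. Histology phantoms emulate three H&E regimes:
# viable tumour (fine high-contrast nuclear speckle), early-apoptotic
# damage (smooth field salted with condensed dark foci) and necrosis
# (large homogeneous low-variance zones). DCE phantoms produce a
# ramp-plateau enhancement over a smooth heterogeneous perfusion field
# with an analytically known AUC. The textures are stylised statistical
# surrogates, not stain renderings: they reproduce the contrast in
# speckle scale, gray-level spread and zone structure that the texture
# features respond to.

phantom_groups <- function() {
  # per-group damaged-area fraction mean/sd and cohort sizes
  tibble::tibble(
    group = c("control", "XRT", "USMB", "USMB_XRT", "USMB_XRT_LOW",
              "USMB_XRT_HIGH"),
    damaged_mean = c(0.112, 0.118, 0.294, 0.291, 0.369, 0.351),
    damaged_sd = c(0.051, 0.006, 0.035, 0.022, 0.048, 0.039),
    n = c(5L, 4L, 5L, 5L, 5L, 5L)
  )
}

# Gaussian blur (sigma in pixels); circular boundary is harmless on the
# stationary noise fields used here
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  rmax <- min(dim(x))
  if (rmax %% 2L == 0L) rmax <- rmax - 1L  # brush size must be odd
  EBImage::imageData(EBImage::gblur(x, sigma = sigma, radius = min(r, rmax)))
}

#' Phantom specification
#'
#' Parameters for one synthetic histology phantom. Group defaults follow
#' the treatment arms of the study design (control, radiation,
#' microbubbles, and their combinations with perfusion-targeted boosts)
#' with per-group damaged-area fractions set to the reported group means.
#'
#' @param group Treatment-group label; one of `control`, `XRT`, `USMB`,
#'   `USMB_XRT`, `USMB_XRT_LOW`, `USMB_XRT_HIGH`.
#' @param image_size Image side in pixels (square; default 480).
#' @param pixel_spacing Micrometres per pixel (default 5, the
#'   post-downsampling scale the pipeline assumes).
#' @param damaged_fraction Target damaged-area fraction; default the
#'   group mean.
#' @param speckle_grain Nuclear speckle grain scale in pixels.
#' @param speckle_contrast Gray-level gap between nuclei and cytoplasm
#'   (0-255 scale).
#' @param necrosis_smoothness Smoothing scale (pixels) of the damaged
#'   field.
#' @param focus_density Condensed-focus density inside damaged areas
#'   (foci per pixel; early-apoptotic salt).
#' @param seed Integer seed fixing the phantom bit-for-bit.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(group = "control", image_size = 480L,
                         pixel_spacing = 5, damaged_fraction = NULL,
                         speckle_grain = 1.2, speckle_contrast = 130,
                         necrosis_smoothness = 6, focus_density = 0.002,
                         seed = 1L) {
  groups <- phantom_groups()
  if (!group %in% groups$group) {
    stop("unknown group '", group, "'", call. = FALSE)
  }
  if (is.null(damaged_fraction)) {
    damaged_fraction <- groups$damaged_mean[groups$group == group]
  }
  if (damaged_fraction < 0 || damaged_fraction > 1) {
    stop("`damaged_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(group = group, image_size = as.integer(image_size),
         pixel_spacing = pixel_spacing,
         damaged_fraction = damaged_fraction,
         speckle_grain = speckle_grain,
         speckle_contrast = speckle_contrast,
         necrosis_smoothness = necrosis_smoothness,
         focus_density = focus_density, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic histology phantom
#'
#' Produces a grayscale image with an elliptical tumour mask and a
#' damaged-region mask realised as connected blobs (a smoothed random
#' field thresholded at the quantile matching the target fraction, so the
#' realised fraction tracks the target). Viable tissue is a fine
#' two-phase nuclear speckle; damaged tissue is a smooth low-variance
#' field salted with small condensed foci.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `image` ([raster_image()]),
#'   `tumor_mask`, `damaged_mask` ([roi_mask()]s), `spec`, and
#'   `realized_fraction`.
#' @export
gen_histology_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$image_size
  # elliptical tumour mask
  cx <- (n + 1) / 2
  rad <- 0.47 * n
  xx <- matrix(seq_len(n), n, n); yy <- t(xx)
  tumor <- ((xx - cx)^2 + (yy - cx)^2) <= rad^2
  if (!any(tumor)) stop("degenerate tumour mask", call. = FALSE)

  # damaged blobs: smooth field thresholded at the target quantile
  target <- spec$damaged_fraction
  damaged <- matrix(FALSE, n, n)
  if (target > 0) {
    field <- gauss_blur(matrix(stats::rnorm(n * n), n, n), n / 8)
    cut <- stats::quantile(field[tumor], probs = 1 - target, names = FALSE)
    damaged <- tumor & field >= cut
    if (target < 1 && !any(damaged & tumor)) {
      stop("damaged fraction target unreachable for this phantom size",
           call. = FALSE)
    }
  }

  # viable regime: fine bimodal nuclear speckle
  u <- gauss_blur(matrix(stats::rnorm(n * n), n, n), spec$speckle_grain)
  nuclei <- u < stats::quantile(u, 0.35, names = FALSE)
  cyto <- 195
  viable_img <- ifelse(nuclei, cyto - spec$speckle_contrast, cyto) +
    matrix(stats::rnorm(n * n, sd = 8), n, n)

  # damaged regime: smooth low-variance field (gentle banding at the
  # necrosis-smoothness scale) with condensed foci
  sm <- gauss_blur(matrix(stats::rnorm(n * n), n, n),
                   spec$necrosis_smoothness)
  sm <- sm / stats::sd(sm)
  base <- 170 + 8 * sm + matrix(stats::rnorm(n * n, sd = 0.5), n, n)
  n_foci <- stats::rpois(1, spec$focus_density * sum(damaged))
  if (n_foci > 0 && any(damaged)) {
    pos <- sample(which(damaged), min(n_foci, sum(damaged)))
    for (p in pos) {
      r <- ((p - 1L) %% n) + 1L; c <- ((p - 1L) %/% n) + 1L
      rr <- max(1L, r - 1L):min(n, r + 1L)
      cc <- max(1L, c - 1L):min(n, c + 1L)
      base[rr, cc] <- 60
    }
  }

  img <- ifelse(damaged, base, viable_img)
  img[!tumor] <- 240  # background (slide white)
  img <- pmin(pmax(img, 0), 255)

  realized <- sum(damaged) / sum(tumor)
  structure(
    list(image = raster_image(img, spec$pixel_spacing,
                              provenance = sprintf("phantom seed %d",
                                                   spec$seed)),
         tumor_mask = roi_mask(tumor, "whole_tumor"),
         damaged_mask = roi_mask(damaged, "damaged"),
         spec = spec, realized_fraction = realized),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> group %s, %d px, damaged fraction %.3f (target %.3f)\n",
    x$spec$group, x$spec$image_size, x$realized_fraction,
    x$spec$damaged_fraction))
  invisible(x)
}

#' Generate a synthetic cohort of histology phantoms
#'
#' Subject-level damaged fractions are drawn from a normal distribution
#' with the group's mean and standard deviation, truncated to `[0, 1]`;
#' per-subject seeds derive deterministically from `base_seed`.
#'
#' @param n_per_group Named integer vector of group sizes; default the
#'   study arm sizes (5, 4, 5, 5, 5, 5).
#' @param base_seed Integer seed for the whole cohort.
#' @param image_size,pixel_spacing Passed to [phantom_spec()].
#' @return A tibble with one row per subject: `subject`, `group`,
#'   `target_fraction`, `realized_fraction`, `seed` and a `phantom`
#'   list-column.
#' @export
gen_cohort <- function(n_per_group = NULL, base_seed = 1L,
                       image_size = 480L, pixel_spacing = 5) {
  groups <- phantom_groups()
  if (is.null(n_per_group)) {
    n_per_group <- stats::setNames(groups$n, groups$group)
  }
  if (any(n_per_group < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  bad <- setdiff(names(n_per_group), groups$group)
  if (length(bad) > 0L) {
    stop("unknown group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(base_seed)
  plan <- purrr::map_dfr(names(n_per_group), function(g) {
    gi <- groups[groups$group == g, ]
    nn <- n_per_group[[g]]
    frac <- pmin(pmax(stats::rnorm(nn, gi$damaged_mean, gi$damaged_sd), 0), 1)
    tibble::tibble(group = g, target_fraction = frac)
  })
  plan$seed <- sample.int(.Machine$integer.max - 1L, nrow(plan))
  plan$subject <- sprintf("S%02d", seq_len(nrow(plan)))
  plan$phantom <- purrr::pmap(
    list(plan$group, plan$target_fraction, plan$seed),
    function(g, f, s) {
      gen_histology_phantom(phantom_spec(
        group = g, image_size = image_size, pixel_spacing = pixel_spacing,
        damaged_fraction = f, seed = s))
    })
  plan$realized_fraction <- vapply(plan$phantom,
                                   function(p) p$realized_fraction,
                                   numeric(1))
  plan[, c("subject", "group", "target_fraction", "realized_fraction",
           "seed", "phantom")]
}

#' Generate a synthetic DCE-MRI series
#'
#' Per voxel, `S(t) = S0 * (1 + k * perfusion * r(t)) + noise` where
#' `r(t)` ramps linearly from 0 at injection to 1 over `t_rise` seconds
#' and then plateaus. The perfusion field is a smooth random field
#' rescaled to `[0.2, 1]`, constant across slices. The analytic
#' baseline-subtracted AUC over a window `W >= t_rise` is
#' `S0 * k * perfusion * (t_rise / 2 + (W - t_rise))`, recorded as ground
#' truth.
#'
#' @param dims Integer vector `(nx, ny, nz, nt)`.
#' @param times Frame times in seconds; default every 6 s from 0.
#' @param baseline_frames Pre-contrast frame indices (default 1:3).
#' @param t_rise Ramp duration in seconds (default 60).
#' @param S0 Baseline signal level (default 100).
#' @param k Enhancement gain (default 1).
#' @param noise_sd Additive white-noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return A list of class `dce_phantom`: `series` ([dce_series()]),
#'   `perfusion` (2D field), `truth_auc` (3D array; analytic AUC over the
#'   first 120 s), `injection_time`, `t_rise`, `k`, `S0`.
#' @export
gen_dce_phantom <- function(dims = c(16L, 16L, 4L, 30L), times = NULL,
                            baseline_frames = 1:3, t_rise = 60, S0 = 100,
                            k = 1, noise_sd = 0, seed = 1L) {
  stopifnot(length(dims) == 4L, dims[4L] >= 4L)
  if (is.null(times)) times <- seq(0, by = 6, length.out = dims[4L])
  set.seed(seed)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]; nt <- dims[4L]
  perf <- gauss_blur(matrix(stats::rnorm(nx * ny), nx, ny), max(nx, ny) / 6)
  perf <- (perf - min(perf)) / max(1e-12, diff(range(perf)))
  perf <- 0.2 + 0.8 * perf
  injection_time <- times[max(baseline_frames) + 1L]
  ramp <- pmin(pmax((times - injection_time) / t_rise, 0), 1)
  sig <- array(0, dims)
  for (t in seq_len(nt)) {
    frame <- S0 * (1 + k * perf * ramp[t])
    for (z in seq_len(nz)) sig[, , z, t] <- frame
  }
  if (noise_sd > 0) {
    sig <- sig + array(stats::rnorm(prod(dims), sd = noise_sd), dims)
  }
  W <- 120
  truth2d <- S0 * k * perf * (t_rise / 2 + (W - t_rise))
  truth <- array(rep(truth2d, nz), c(nx, ny, nz))
  structure(
    list(series = dce_series(sig, times, baseline_frames),
         perfusion = perf, truth_auc = truth,
         injection_time = injection_time, t_rise = t_rise, k = k, S0 = S0),
    class = "dce_phantom"
  )
}
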
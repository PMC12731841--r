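# End-to-end analysis: phantom (or image + masks) -> quantization ->
# first-pass features per region -> texture maps + medians ->
# texture-derivative features -> group statistics.

#' Analyse one subject's histology image
#'
#' Normalises and quantizes the grayscale image per region, extracts the
#' 59 first-pass features for the whole-tumour and damaged regions,
#' computes whole-tumour texture maps with their medians, and derives
#' second-pass texture-derivative features from those maps.
#'
#' @param image A [raster_image()] (grayscale or RGB).
#' @param tumor_mask,damaged_mask [roi_mask()]s aligned with the image
#'   (`damaged_mask` may be all-false).
#' @param params A [texture_params()].
#' @param block_mm,min_coverage Texture-map tiling, see [tile_roi()].
#' @param Ng2 Second-pass gray-level count.
#' @param with_maps,with_derivatives Disable the windowed stages to save
#'   time.
#' @return A list with tibbles `features`, `map_medians`, `derivatives`
#'   and the scalar `damaged_fraction`.
#' @export
analyze_image <- function(image, tumor_mask, damaged_mask = NULL,
                          params = texture_params(), block_mm = 0.5,
                          min_coverage = 0.5, Ng2 = 16L,
                          with_maps = TRUE, with_derivatives = TRUE) {
  img <- normalize_intensity(to_grayscale(image))
  q_tumor <- quantize(img, tumor_mask, Ng = params$Ng)
  features <- extract_all(q_tumor, params = params, region = "whole_tumor")
  dfrac <- NA_real_
  if (!is.null(damaged_mask)) {
    dm <- if (inherits(damaged_mask, "roi_mask")) damaged_mask$mask
          else damaged_mask
    dfrac <- damaged_fraction(damaged_mask, tumor_mask)
    if (any(dm)) {
      q_dmg <- quantize(img, damaged_mask, Ng = params$Ng)
      features <- dplyr::bind_rows(
        features,
        extract_all(q_dmg, params = params, region = "damaged"))
    }
  }
  map_medians <- NULL; derivatives <- NULL
  if (with_maps) {
    grid <- tile_roi(q_tumor, tumor_mask, block_mm = block_mm,
                     min_coverage = min_coverage)
    if (sum(grid$blocks$valid) >= 1L) {
      maps <- compute_texture_map(q_tumor, tumor_mask, grid,
                                  params = params)
      map_medians <- map_medians(maps)
      if (with_derivatives) {
        derivatives <- derivative_features(maps, Ng2 = Ng2,
                                           params = params)
      }
    } else {
      warning("no valid texture-map blocks; skipping windowed stages")
    }
  }
  list(features = features, map_medians = map_medians,
       derivatives = derivatives, damaged_fraction = dfrac)
}

#' Run the full cohort analysis
#'
#' Applies [analyze_image()] to every subject of a [gen_cohort()] tibble
#' (or any tibble with `subject`, `group` and `phantom` columns), stacks
#' the per-subject results into tier tables, and runs group statistics on
#' each tier.
#'
#' @param cohort A cohort tibble from [gen_cohort()].
#' @param outdir Optional directory; when given, tier CSVs and the
#'   statistics summaries are written via [report()].
#' @param alpha Significance level for the pairwise tests.
#' @inheritParams analyze_image
#' @return A list: `damaged` (per-subject fractions), `features`,
#'   `map_medians`, `derivatives` tier tibbles, and `stats` (a named list
#'   of [compare_groups()] results per tier).
#' @export
run_cohort_analysis <- function(cohort, outdir = NULL,
                                params = texture_params(), block_mm = 0.5,
                                min_coverage = 0.5, Ng2 = 16L,
                                with_maps = TRUE, with_derivatives = TRUE,
                                alpha = 0.05) {
  stopifnot(all(c("subject", "group", "phantom") %in% names(cohort)))
  res <- purrr::pmap(
    list(cohort$subject, cohort$group, cohort$phantom),
    function(subj, grp, ph) {
      a <- analyze_image(ph$image, ph$tumor_mask, ph$damaged_mask,
                         params = params, block_mm = block_mm,
                         min_coverage = min_coverage, Ng2 = Ng2,
                         with_maps = with_maps,
                         with_derivatives = with_derivatives)
      list(
        damaged = tibble::tibble(subject = subj, group = grp,
                                 damaged_fraction = a$damaged_fraction),
        features = tibble::tibble(subject = subj, group = grp,
                                  a$features),
        map_medians = if (!is.null(a$map_medians)) {
          tibble::tibble(subject = subj, group = grp, a$map_medians)
        },
        derivatives = if (!is.null(a$derivatives)) {
          tibble::tibble(subject = subj, group = grp, a$derivatives)
        })
    })
  damaged <- purrr::map_dfr(res, "damaged")
  features <- purrr::map_dfr(res, "features")
  medians <- purrr::map_dfr(res, "map_medians")
  derivs <- purrr::map_dfr(res, "derivatives")

  long <- function(d, value_col, key_cols) {
    tibble::tibble(subject = d$subject, group = d$group,
                   feature = do.call(paste, d[key_cols]),
                   value = d[[value_col]])
  }
  stats <- list(
    damaged = compare_groups(
      tibble::tibble(subject = damaged$subject, group = damaged$group,
                     feature = "damaged_fraction",
                     value = damaged$damaged_fraction), alpha = alpha))
  tiers <- list(damaged = damaged)
  for (region in unique(features$region)) {
    d <- features[features$region == region, ]
    stats[[paste0("features_", region)]] <-
      compare_groups(long(d, "value", c("family", "feature")),
                     alpha = alpha)
  }
  tiers$features <- features
  if (nrow(medians) > 0L) {
    stats$map_medians <- compare_groups(
      long(medians, "median", c("family", "feature")), alpha = alpha)
    tiers$map_medians <- medians
  }
  if (nrow(derivs) > 0L) {
    ok <- derivs[derivs$computed & is.finite(derivs$value), ]
    stats$derivatives <- compare_groups(
      long(ok, "value", c("map_family", "name")), alpha = alpha)
    tiers$derivatives <- derivs
  }
  if (!is.null(outdir)) {
    report(tiers, NULL, outdir)
    for (nm in names(stats)) {
      an <- as.data.frame(stats[[nm]]$anova)
      an <- an[order(an$feature), , drop = FALSE]
      utils::write.csv(an, file.path(outdir,
                                     paste0("anova_", nm, ".csv")),
                       row.names = FALSE)
      pw <- as.data.frame(stats[[nm]]$pairwise)
      pw <- pw[order(pw$feature, pw$group1, pw$group2), , drop = FALSE]
      utils::write.csv(pw, file.path(outdir,
                                     paste0("pairwise_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  list(damaged = damaged, features = features, map_medians = medians,
       derivatives = derivs, stats = stats)
}
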
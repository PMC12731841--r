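# Full first-pass feature extraction: 59 features across four matrix
# families (24 GLCM + 16 GLSZM + 14 GLDM + 5 NGTDM).

#' Texture analysis parameter set
#'
#' Collects the tunable knobs shared across the pipeline. Defaults: 32
#' gray levels, GLCM distance 1 with the four 2D directions (symmetric,
#' features averaged over directions), GLDM tolerance 0 at Chebyshev
#' distance 1, NGTDM over the eight surrounding pixels.
#'
#' @param Ng Gray levels for first-pass quantization.
#' @param glcm_distance GLCM pair distance in pixels.
#' @param glcm_symmetric Symmetric GLCM accumulation.
#' @param gldm_alpha GLDM dependence tolerance.
#' @param gldm_distance GLDM Chebyshev radius.
#' @param ngtdm_distance NGTDM Chebyshev radius.
#' @return A named list of class `texture_params`.
#' @export
texture_params <- function(Ng = 32L, glcm_distance = 1L,
                           glcm_symmetric = TRUE, gldm_alpha = 0,
                           gldm_distance = 1L, ngtdm_distance = 1L) {
  structure(
    list(Ng = as.integer(Ng), glcm_distance = as.integer(glcm_distance),
         glcm_symmetric = isTRUE(glcm_symmetric), gldm_alpha = gldm_alpha,
         gldm_distance = as.integer(gldm_distance),
         ngtdm_distance = as.integer(ngtdm_distance)),
    class = "texture_params"
  )
}

#' Names of the 59 first-pass texture features
#'
#' @param family Optional subset of `"GLCM"`, `"GLSZM"`, `"GLDM"`,
#'   `"NGTDM"`.
#' @return A tibble with columns `family` and `feature` (59 rows for the
#'   full set, partitioned 24/16/14/5).
#' @export
feature_names <- function(family = c("GLCM", "GLSZM", "GLDM", "NGTDM")) {
  family <- match.arg(family, several.ok = TRUE)
  lv1 <- matrix(1L, 2L, 2L)
  q1 <- quantized_image(lv1, 2L, c(0, 0.5, 1), 1)
  tabs <- list(
    GLCM = glcm_features(compute_glcm(q1)),
    GLSZM = glszm_features(compute_glszm(q1)),
    GLDM = gldm_features(compute_gldm(q1)),
    NGTDM = ngtdm_features(compute_ngtdm(q1))
  )
  dplyr::bind_rows(tabs[family])[, c("family", "feature")]
}

#' Extract all 59 first-pass texture features
#'
#' Builds the four texture matrices on a quantized image (optionally
#' restricted to an ROI) and concatenates their feature vectors in a fixed
#' order: 24 GLCM, 16 GLSZM, 14 GLDM, 5 NGTDM.
#'
#' @param q A [quantized_image()].
#' @param roi Optional [roi_mask()] restricting the analysis.
#' @param params A [texture_params()].
#' @param region Label stored in the `region` column (default taken from
#'   the ROI label, or `"all"`).
#' @return A tibble with columns `region`, `family`, `feature`, `value`
#'   (59 rows).
#' @export
extract_all <- function(q, roi = NULL, params = texture_params(),
                        region = NULL) {
  stopifnot(inherits(q, "quantized_image"))
  if (is.null(region)) {
    region <- if (inherits(roi, "roi_mask")) roi$label else "all"
  }
  out <- dplyr::bind_rows(
    glcm_features(compute_glcm(q, roi, distance = params$glcm_distance,
                               symmetric = params$glcm_symmetric)),
    glszm_features(compute_glszm(q, roi)),
    gldm_features(compute_gldm(q, roi, alpha = params$gldm_alpha,
                               distance = params$gldm_distance)),
    ngtdm_features(compute_ngtdm(q, roi, distance = params$ngtdm_distance))
  )
  tibble::tibble(region = region, out)
}
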
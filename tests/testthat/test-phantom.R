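test_that("phantom generation is reproducible from the seed", {
  s <- phantom_spec(group = "USMB", image_size = 120L, seed = 11L)
  p1 <- gen_histology_phantom(s)
  p2 <- gen_histology_phantom(s)
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$damaged_mask$mask, p2$damaged_mask$mask)
  p3 <- gen_histology_phantom(phantom_spec(group = "USMB",
                                           image_size = 120L, seed = 12L))
  expect_false(identical(p1$damaged_mask$mask, p3$damaged_mask$mask))
})

test_that("the realized damaged fraction tracks its target", {
  for (target in c(0.1, 0.25, 0.369)) {
    p <- gen_histology_phantom(phantom_spec(
      image_size = 240L, damaged_fraction = target, seed = 5L))
    expect_lt(abs(p$realized_fraction - target), 0.02)
    expect_true(all(!p$damaged_mask$mask | p$tumor_mask$mask))
  }
})

test_that("group defaults carry the study damaged-area means", {
  expect_equal(phantom_spec(group = "USMB_XRT_LOW")$damaged_fraction, 0.369)
  expect_equal(phantom_spec(group = "control")$damaged_fraction, 0.112)
  expect_error(phantom_spec(group = "placebo"), "unknown group")
  expect_error(phantom_spec(damaged_fraction = 1.2), "\\[0, 1\\]")
})

test_that("the default cohort has 29 subjects in six groups", {
  cohort <- gen_cohort(base_seed = 3L, image_size = 64L)
  expect_equal(nrow(cohort), 29L)
  expect_equal(sort(unique(cohort$group)),
               sort(c("control", "XRT", "USMB", "USMB_XRT",
                      "USMB_XRT_LOW", "USMB_XRT_HIGH")))
  cohort2 <- gen_cohort(base_seed = 3L, image_size = 64L)
  expect_identical(cohort$phantom[[7]]$image$pixels,
                   cohort2$phantom[[7]]$image$pixels)
  cohort3 <- gen_cohort(base_seed = 4L, image_size = 64L)
  expect_false(identical(cohort$phantom[[1]]$damaged_mask$mask,
                         cohort3$phantom[[1]]$damaged_mask$mask))
})

test_that("noise-free DCE phantoms recover the analytic AUC", {
  ph <- gen_dce_phantom(seed = 9L)
  a <- auc_initial(ph$series, injection_time = ph$injection_time,
                   window = 120)
  rel <- abs(a$auc - ph$truth_auc) / ph$truth_auc
  expect_lt(max(rel), 0.01)
})

test_that("enhancement gain scales AUC linearly but not auc_norm", {
  p1 <- gen_dce_phantom(k = 1, seed = 13L)
  p2 <- gen_dce_phantom(k = 2, seed = 13L)
  a1 <- auc_initial(p1$series, injection_time = p1$injection_time)
  a2 <- auc_initial(p2$series, injection_time = p2$injection_time)
  expect_equal(a2$auc, 2 * a1$auc, tolerance = 1e-9)
  muscle <- array(FALSE, dim(a1$auc)); muscle[1:4, 1, 1] <- TRUE
  n1 <- normalize_auc(a1, muscle); n2 <- normalize_auc(a2, muscle)
  expect_equal(n1$auc_norm, n2$auc_norm, tolerance = 1e-9)
})

test_that("a constant perfusion field degrades to the tie-break rule", {
  ph <- gen_dce_phantom(seed = 15L)
  # overwrite with a flat field by hand: constant series
  sig <- ph$series$signal
  sig[] <- rep(100 * (1 + 0.5 * pmin(pmax((ph$series$times - ph$injection_time) / 60, 0), 1)),
               each = prod(dim(sig)[1:3]))
  s <- dce_series(sig, ph$series$times, ph$series$baseline_frames)
  a <- auc_initial(s, injection_time = ph$injection_time)
  mip <- mip_transverse(a)
  expect_warning(ex <- exclusion_mask(mip, matrix(TRUE, nrow(mip), ncol(mip)),
                                      "low_target"), "tie")
  expect_equal(ex$n_excluded, ceiling(length(mip) / 3))
})
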
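make_series <- function(curve, baseline = 1:2, dims = c(2L, 2L, 2L)) {
  nt <- length(curve)
  sig <- array(rep(curve, each = prod(dims)), c(dims, nt))
  dce_series(sig, seq(0, by = 30, length.out = nt), baseline)
}

test_that("percentage enhancement follows its definition", {
  s <- make_series(c(100, 100, 150, 120))
  pe <- percent_enhancement(s)
  expect_equal(pe$enhancement_pct, c(0, 0, 50, 20))

  # multi-frame baseline {90, 110} -> S0 = 100
  s2 <- make_series(c(90, 110, 150, 150))
  expect_equal(percent_enhancement(s2)$enhancement_pct[3], 50)

  # flat signal -> identically zero
  s3 <- make_series(c(80, 80, 80, 80))
  expect_true(all(percent_enhancement(s3)$enhancement_pct == 0))

  s4 <- make_series(c(0, 0, 10, 10))
  expect_error(percent_enhancement(s4), "positive")
})

test_that("initial AUC is the trapezoidal integral of enhancement", {
  # baseline-subtracted 0 @ 0 s, 40 @ 60 s, 60 @ 120 s -> 4200 signal s
  sig <- array(rep(c(100, 100, 140, 160), each = 8), c(2, 2, 2, 4))
  s <- dce_series(sig, c(-30, 0, 60, 120), baseline_frames = 1:2)
  a <- auc_initial(s, injection_time = 0, window = 120)
  expect_true(all(abs(a$auc - 4200) < 1e-9))

  # flat signal integrates to zero; doubled enhancement doubles the AUC
  flat <- make_series(rep(100, 6))
  expect_true(all(auc_initial(flat, injection_time = 30,
                              window = 60)$auc == 0))
  sig2 <- sig; sig2[, , , 3:4] <- 100 + 2 * (sig[, , , 3:4] - 100)
  s2 <- dce_series(sig2, c(-30, 0, 60, 120), baseline_frames = 1:2)
  a2 <- auc_initial(s2, injection_time = 0, window = 120)
  expect_equal(a2$auc, 2 * a$auc)
})

test_that("a window past the last frame truncates with a warning", {
  s <- make_series(c(100, 100, 150, 150))
  expect_warning(a <- auc_initial(s, injection_time = 60, window = 120),
                 "truncating")
  expect_true(all(is.finite(a$auc)))
})

test_that("muscle normalisation divides by the reference mean", {
  sig <- array(rep(c(100, 100, 140, 160), each = 8), c(2, 2, 2, 4))
  s <- dce_series(sig, c(-30, 0, 60, 120), baseline_frames = 1:2)
  a <- auc_initial(s, injection_time = 0)
  muscle <- array(FALSE, c(2, 2, 2)); muscle[1, 1, ] <- TRUE
  an <- normalize_auc(a, muscle)
  expect_equal(an$muscle_auc, 4200)
  expect_true(all(abs(an$auc_norm - 1) < 1e-9))  # muscle == tumour here

  # global rescaling of the series leaves auc_norm unchanged
  s3 <- dce_series(3 * sig, c(-30, 0, 60, 120), baseline_frames = 1:2)
  an3 <- normalize_auc(auc_initial(s3, injection_time = 0), muscle)
  expect_equal(an3$auc_norm, an$auc_norm)

  zero <- auc_initial(make_series(rep(100, 4)), injection_time = 30,
                      window = 60)
  expect_error(normalize_auc(zero, muscle), "positive")
})

test_that("the transverse MIP is the per-column maximum over slices", {
  vol <- array(0, c(4, 4, 3))
  set.seed(81)
  vol[] <- runif(48)
  a <- structure(list(auc = vol, auc_norm = NULL), class = "auc_map")
  mip <- mip_transverse(a)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(mip[i, j], max(vol[i, j, ]))
  }
  single <- structure(list(auc = vol[, , 1, drop = FALSE],
                           auc_norm = NULL), class = "auc_map")
  expect_equal(unclass(mip_transverse(single)), vol[, , 1],
               ignore_attr = TRUE)
})

test_that("tertile exclusion keeps exactly two thirds of distinct voxels", {
  mip <- matrix(1:9, 3, 3)
  tumor <- matrix(TRUE, 3, 3)
  lo <- exclusion_mask(mip, tumor, "low_target")
  expect_equal(sort(mip[lo$excluded]), c(7, 8, 9))
  expect_equal(lo$n_kept, 6L)
  expect_equal(lo$treated_pct, 66)

  hi <- exclusion_mask(mip, tumor, "high_target")
  expect_equal(sort(mip[hi$excluded]), c(1, 2, 3))
  expect_equal(hi$treated_pct, 66)

  # the two modes exclude disjoint sets when values are distinct
  expect_true(!any(lo$excluded & hi$excluded))
})

test_that("tertile exclusion handles ties and non-divisible counts", {
  mip <- matrix(5, 3, 3)
  expect_warning(r <- exclusion_mask(mip, matrix(TRUE, 3, 3), "low_target"),
                 "tie")
  expect_equal(r$n_excluded, 3L)

  mip2 <- matrix(c(1:10, rep(0, 6)), 4, 4)
  tumor2 <- matrix(FALSE, 4, 4); tumor2[1:10] <- TRUE
  r2 <- exclusion_mask(mip2, tumor2, "low_target")
  expect_equal(r2$n_excluded, ceiling(10 / 3))
  expect_equal(r2$n_kept, floor(2 * 10 / 3))
})

test_that("the 18 mm region divides into 15 x 15 cells of 1.2 mm", {
  g <- build_cell_grid(18, 1.2, voxel_spacing = 0.6)
  expect_equal(g$n_cells, 15L)
  expect_equal(nrow(g$cells), 225L)
  # single cell when the cell spans the whole region
  g1 <- build_cell_grid(18, 18, voxel_spacing = 0.6)
  expect_equal(g1$n_cells, 1L)
  expect_error(build_cell_grid(18, 20, 0.6), "exceed")
})

test_that("in-region voxels are assigned to exactly one cell", {
  g <- build_cell_grid(18, 1.2, voxel_spacing = 0.6)  # 30 x 30 voxels
  cover <- matrix(0L, 30, 30)
  for (k in seq_len(nrow(g$cells))) {
    b <- g$cells[k, ]
    if (b$r0 > b$r1 || b$c0 > b$c1) next
    cover[b$r0:b$r1, b$c0:b$c1] <- cover[b$r0:b$r1, b$c0:b$c1] + 1L
  }
  expect_true(all(cover <= 1L))
  expect_true(all(cover[8:23, 8:23] == 1L))  # central region fully tiled
})

test_that("any excluded voxel removes its treatment cell", {
  g <- build_cell_grid(6, 2, voxel_spacing = 1)  # 3 x 3 cells of 2 px
  mip <- matrix(seq_len(36) %% 7, 6, 6)
  tumor <- matrix(TRUE, 6, 6)
  ex <- suppressWarnings(exclusion_mask(mip, tumor, "low_target"))
  cells <- apply_exclusion_to_cells(g, ex)
  for (k in which(cells$in_region & cells$n_voxels > 0)) {
    b <- cells[k, ]
    has_excl <- any(ex$excluded[b$r0:b$r1, b$c0:b$c1])
    expect_equal(cells$kept[k], !has_excl)
  }
  # cell-level treated volume never exceeds voxel-level
  kept_cell_vox <- sum(cells$n_voxels[cells$kept])
  expect_lte(kept_cell_vox, ex$n_kept)
})
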
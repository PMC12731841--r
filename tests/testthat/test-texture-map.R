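test_that("tiling arithmetic follows block size and pixel spacing", {
  # 300 x 200 px full-rectangle ROI at 5 um/px with 0.5 mm blocks:
  # 100 px blocks in a 3 x 2 grid (rows x cols), all 6 valid
  lv <- matrix(1L, 300, 200)
  q <- qimg(lv, 2, spacing = 5)
  grid <- tile_roi(q, matrix(TRUE, 300, 200))
  expect_equal(grid$block_px, 100L)
  expect_equal(c(grid$n_rows, grid$n_cols), c(3L, 2L))
  expect_equal(sum(grid$blocks$valid), 6L)
  expect_true(all(grid$blocks$coverage == 1))
})

test_that("partially covered boundary blocks obey the admission threshold", {
  # circular ROI (radius 200 px) over a 4 x 4 grid of 100 px blocks: the
  # corner blocks cover ~1/4 of their window and are rejected at 0.5
  n <- 400L
  cx <- (n + 1) / 2
  xx <- matrix(seq_len(n), n, n); yy <- t(xx)
  roi <- (xx - cx)^2 + (yy - cx)^2 <= 200^2
  lv <- matrix(1L, n, n); lv[!roi] <- 0L
  q <- qimg(lv, 2, spacing = 5)
  grid <- tile_roi(q, roi, block_mm = 0.5, min_coverage = 0.5)
  expect_equal(c(grid$n_rows, grid$n_cols), c(4L, 4L))
  b <- grid$blocks
  corners <- b$row %in% c(1L, 4L) & b$col %in% c(1L, 4L)
  expect_true(all(!b$valid[corners]))
  expect_true(all(b$valid[b$row %in% 2:3 & b$col %in% 2:3]))
  expect_true(all(!b$valid | b$coverage >= 0.5))
  # threshold off: every intersecting block is admitted
  grid0 <- tile_roi(q, roi, block_mm = 0.5, min_coverage = 0)
  expect_true(all(grid0$blocks$valid))
})

test_that("an oversized block yields zero valid blocks with a warning", {
  q <- qimg(matrix(1L, 20, 20), 2, spacing = 5)
  expect_warning(grid <- tile_roi(q, matrix(TRUE, 20, 20), block_mm = 0.5),
                 "no valid blocks")
  expect_equal(nrow(grid$blocks), 0L)
})

test_that("maps over a constant image are constant at the feature limit", {
  q <- qimg(matrix(1L, 40, 40), 2, spacing = 25)  # 0.5 mm = 20 px
  roi <- matrix(TRUE, 40, 40)
  grid <- tile_roi(q, roi)
  maps <- compute_texture_map(q, roi, grid,
                              features = c("GLCM Contrast",
                                           "GLCM Joint Energy"))
  expect_true(all(maps[["GLCM Contrast"]]$values[maps[["GLCM Contrast"]]$valid] == 0))
  expect_true(all(maps[["GLCM Joint Energy"]]$values == 1))
  expect_equal(map_median(maps[["GLCM Joint Energy"]]), 1)
})

test_that("a single-block map equals direct extraction on that window", {
  set.seed(61)
  lv <- random_levels(20, 20, 5)
  q <- qimg(lv, 5, spacing = 25)  # exactly one 20 px block
  roi <- matrix(TRUE, 20, 20)
  grid <- tile_roi(q, roi)
  expect_equal(sum(grid$blocks$valid), 1L)
  maps <- compute_texture_map(q, roi, grid)
  direct <- extract_all(q)
  for (k in seq_len(nrow(direct))) {
    key <- paste(direct$family[k], direct$feature[k])
    expect_equal(maps[[key]]$values[1, 1], direct$value[k],
                 tolerance = 1e-12)
  }
})

test_that("speckled half-images produce higher contrast map values", {
  set.seed(62)
  n <- 60L
  lv <- cbind(checkerboard(n)[, 1:(n / 2)] ,
              matrix(1L, n, n / 2))
  storage.mode(lv) <- "integer"
  q <- qimg(lv, 2, spacing = 50)  # 0.5 mm = 10 px -> 6 x 6 blocks
  roi <- matrix(TRUE, n, n)
  grid <- tile_roi(q, roi)
  maps <- compute_texture_map(q, roi, grid, features = "GLCM Contrast")
  m <- maps[["GLCM Contrast"]]
  left <- mean(m$values[, 1:3])
  right <- mean(m$values[, 4:6])
  expect_gt(left, right)
})

test_that("map medians follow the masking and even-count rules", {
  vals <- matrix(c(1, 2, 3, 100), 2, 2)
  valid <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  m <- texture_map("Contrast", "GLCM", vals, valid, 0.5)
  expect_equal(map_median(m), 2)  # invalid 100 excluded
  m2 <- texture_map("Contrast", "GLCM", matrix(1:4, 2, 2),
                    matrix(TRUE, 2, 2), 0.5)
  expect_equal(map_median(m2), 2.5)
  m3 <- texture_map("Contrast", "GLCM", vals, matrix(FALSE, 2, 2), 0.5)
  expect_error(map_median(m3), "no valid blocks")
})

test_that("unknown feature names are rejected", {
  q <- qimg(matrix(1L, 20, 20), 2, spacing = 25)
  grid <- tile_roi(q, matrix(TRUE, 20, 20))
  expect_error(
    compute_texture_map(q, matrix(TRUE, 20, 20), grid,
                        features = "Banana Emphasis"),
    "unknown feature")
})
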
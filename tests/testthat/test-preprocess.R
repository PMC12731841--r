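test_that("images round-trip through disk in both formats", {
  set.seed(42)
  px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  img <- raster_image(px, pixel_spacing = 5)
  for (ext in c("tif", "png")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_image(img, path)
    back <- load_image(path, pixel_spacing = 5)
    expect_equal(back$pixels, px, tolerance = 1e-3)
    expect_equal(back$pixel_spacing, 5)
  }
})

test_that("loading a missing or unsupported file errors", {
  expect_error(load_image("no/such/file.png", 5), "does not exist")
  path <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", path)
  expect_error(load_image(path, 5), "unsupported")
})

test_that("downsample computes block means and rescales spacing", {
  const <- raster_image(matrix(7, 20, 20), 5)
  out <- downsample(const, 10L)
  expect_equal(dim(out$pixels), c(2L, 2L))
  expect_true(all(out$pixels == 7))
  expect_equal(out$pixel_spacing, 50)

  hand <- raster_image(matrix(c(0, 4, 2, 6), 2, 2), 1)  # [[0,2],[4,6]]
  expect_equal(downsample(hand, 2L)$pixels, matrix(3, 1, 1))

  img <- raster_image(matrix(runif(25), 5, 5), 2)
  expect_identical(downsample(img, 1L), img)
  # trailing remainder rows/cols are dropped
  expect_equal(dim(downsample(img, 2L)$pixels), c(2L, 2L))
  expect_error(downsample(img, 0), "positive integer")
})

test_that("grayscale conversion uses BT.601 weights and is idempotent", {
  gray_rgb <- raster_image(array(120, c(3, 3, 3)), 5)
  # the canonical weights sum to 0.9999, so gray input is a fixed point
  # only to that accuracy
  expect_equal(to_grayscale(gray_rgb)$pixels, matrix(120, 3, 3),
               tolerance = 2e-4)

  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(to_grayscale(raster_image(red, 5))$pixels[1, 1],
               0.2989 * 255, tolerance = 1e-10)

  scalar <- raster_image(matrix(33, 2, 2), 5)
  expect_identical(to_grayscale(scalar), scalar)
  expect_identical(to_grayscale(to_grayscale(scalar)), scalar)
})

test_that("intensity normalisation maps the range onto [0, 255]", {
  img <- raster_image(matrix(c(10, 20, 30, 40), 2, 2), 5)
  out <- normalize_intensity(img)
  expect_equal(range(out$pixels), c(0, 255))
  expect_equal(out$pixels[1, 1], 0)
  # constant image maps to zero rather than dividing by zero
  expect_true(all(normalize_intensity(
    raster_image(matrix(9, 2, 2), 5))$pixels == 0))
})

test_that("quantization bins in-ROI intensities and is monotone", {
  img <- raster_image(matrix(0:255, 16, 16), 5)
  roi <- roi_mask(matrix(TRUE, 16, 16))
  q <- quantize(img, roi, Ng = 2L)
  expect_identical(sort(unique(as.vector(q$levels))), c(1L, 2L))
  expect_true(all(q$levels[img$pixels < 127.5] == 1L))
  expect_true(all(q$levels[img$pixels >= 127.5] == 2L))

  # monotone: level(a) <= level(b) whenever a <= b
  set.seed(1)
  img2 <- raster_image(matrix(runif(100, 0, 255), 10, 10), 5)
  q2 <- quantize(img2, matrix(TRUE, 10, 10), Ng = 7L)
  ord <- order(img2$pixels)
  expect_true(all(diff(q2$levels[ord]) >= 0))
  expect_true(all(q2$levels >= 1L & q2$levels <= 7L))
})

test_that("quantization handles degenerate and masked input", {
  img <- raster_image(matrix(5, 4, 4), 5)
  q <- quantize(img, matrix(TRUE, 4, 4), Ng = 8L)
  expect_true(all(q$levels == 1L))
  expect_equal(q$Ng, 8L)
  expect_true(all(diff(q$bin_edges) > 0))

  roi <- matrix(FALSE, 4, 4); roi[2, 2] <- TRUE
  q2 <- quantize(img, roi, Ng = 4L)
  expect_equal(sum(q2$levels > 0L), 1L)
  expect_true(all(q2$levels[!roi] == 0L))
  expect_error(quantize(img, matrix(FALSE, 4, 4), 4L), "empty")
})
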
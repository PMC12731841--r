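make_table <- function(values_by_group) {
  purrr::imap_dfr(values_by_group, function(v, g) {
    tibble::tibble(subject = paste0(g, seq_along(v)), group = g,
                   feature = "f", value = v)
  })
}

test_that("damaged fraction is the masked area ratio", {
  tumor <- matrix(FALSE, 10, 10); tumor[1:10, 1:10] <- TRUE
  damaged <- matrix(FALSE, 10, 10); damaged[1:5, 1:5] <- TRUE
  expect_equal(damaged_fraction(damaged, tumor), 0.25)
  expect_equal(damaged_fraction(tumor, tumor), 1.0)
  expect_equal(damaged_fraction(matrix(FALSE, 10, 10), tumor), 0)
  # damage outside the tumour does not count
  tum2 <- matrix(FALSE, 10, 10); tum2[1:2, 1:2] <- TRUE
  dmg2 <- matrix(FALSE, 10, 10); dmg2[9:10, 9:10] <- TRUE
  expect_equal(damaged_fraction(dmg2, tum2), 0)
  expect_error(damaged_fraction(dmg2, matrix(FALSE, 10, 10)), "empty")
})

test_that("one-way ANOVA matches the hand decomposition on fixed input", {
  r <- one_way_anova(make_table(list(a = c(1, 2), b = c(3, 4))), "f")
  expect_equal(r$statistic, 8)
  expect_equal(r$r_squared, 0.8)
  r0 <- one_way_anova(make_table(list(a = c(1, 2, 3), b = c(1, 2, 3))), "f")
  expect_equal(r0$statistic, 0)
})

test_that("ANOVA F and R2 match the sum-of-squares oracle on random tables", {
  set.seed(91)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), mean = i))
    names(vals) <- paste0("g", seq_len(k))
    tab <- make_table(vals)
    r <- one_way_anova(tab, "f")
    # independent oracle: explicit between/within sums of squares
    gm <- mean(tab$value)
    ssb <- sum(vapply(vals, function(v) length(v) * (mean(v) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
    dfb <- k - 1; dfw <- nrow(tab) - k
    f_oracle <- (ssb / dfb) / (ssw / dfw)
    expect_equal(r$statistic, f_oracle, tolerance = 1e-10)
    expect_equal(r$r_squared, ssb / (ssb + ssw), tolerance = 1e-10)
    expect_equal(r$p_value, stats::pf(f_oracle, dfb, dfw, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_true(r$r_squared >= 0 && r$r_squared <= 1)
  }
})

test_that("degenerate zero-variance tables warn and report F = 0", {
  tab <- make_table(list(a = c(2, 2), b = c(2, 2)))
  expect_warning(r <- one_way_anova(tab, "f"), "identical")
  expect_equal(r$statistic, 0)
  expect_error(one_way_anova(make_table(list(a = c(1, 2), b = 3)), "f"),
               "fewer than two")
})

test_that("tidy and glance return broom-shaped tibbles", {
  r <- one_way_anova(make_table(list(a = c(1, 2), b = c(3, 4))), "f")
  td <- tidy(r)
  expect_equal(td$term, c("group", "residuals"))
  expect_equal(td$sumsq, c(4, 1))
  gl <- glance(r)
  expect_equal(gl$statistic, 8)
  expect_equal(gl$r.squared, 0.8)
  expect_equal(gl$nobs, 4L)
})

test_that("Bonferroni adjustment multiplies by the pair count and caps at 1", {
  set.seed(92)
  tab <- make_table(list(a = rnorm(4), b = rnorm(4, 2), c = rnorm(4, 4)))
  pw <- bonferroni_pairwise(tab, "f")
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_bonferroni, pmin(1, pw$p_raw * 3))
  expect_true(all(pw$p_bonferroni >= pw$p_raw))
  expect_true(all(pw$p_bonferroni <= 1))

  # identical groups: t = 0, raw p = 1, never significant
  tab2 <- make_table(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  pw2 <- bonferroni_pairwise(tab2, "f")
  expect_equal(pw2$p_raw, 1)
  expect_false(pw2$significant)

  # raw p recovers the pooled-variance two-sample t test
  x <- tab$value[tab$group == "a"]; y <- tab$value[tab$group == "b"]
  expect_equal(pw$p_raw[pw$group1 == "a" & pw$group2 == "b"],
               stats::t.test(x, y, var.equal = TRUE)$p.value)
})

test_that("report writes deterministic CSVs and errors on empty input", {
  tab <- make_table(list(a = c(1, 2), b = c(3, 4)))
  res <- compare_groups(tab)
  d1 <- withr::local_tempdir()
  report(list(features = tab), res, d1)
  files <- sort(list.files(d1))
  expect_equal(files, c("anova_summary.csv", "features.csv",
                        "pairwise_summary.csv"))
  first <- readLines(file.path(d1, "features.csv"))
  report(list(features = tab), res, d1)
  expect_identical(readLines(file.path(d1, "features.csv")), first)
  expect_error(report(list(), NULL, d1))
})
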
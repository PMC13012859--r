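test_that("the catalogue reproduces the published family counts", {
  cat <- feature_catalogue()
  expect_equal(nrow(cat), 868L)
  counts <- table(cat$family)
  expect_equal(unname(counts["clinical"]), 8L)
  expect_equal(unname(counts["shape"]), 14L)
  expect_equal(unname(counts["histogram"]), 9L)
  expect_equal(unname(counts["fo"]), 162L)
  expect_equal(unname(counts["glcm"]), 216L)
  expect_equal(unname(counts["glrlm"]), 144L)
  expect_equal(unname(counts["glszm"]), 144L)
  expect_equal(unname(counts["gldm"]), 126L)
  expect_equal(unname(counts["ngtdm"]), 45L)
  expect_equal(anyDuplicated(cat$name), 0L)
  # catalogue arithmetic: 8 + 14 + 9 + 9 * (18 + 24 + 16 + 16 + 14 + 5)
  expect_equal(8 + 14 + 9 + 9 * (18 + 24 + 16 + 16 + 14 + 5), 868)
})

test_that("histogram features put the median first and handle degeneracy", {
  f <- histogram_features(c(1, 2, 3, 4, 5))
  expect_equal(names(f)[1], "hist_Median")
  expect_equal(unname(f["hist_Median"]), 3)
  fc <- histogram_features(rep(2.5, 40))
  expect_equal(unname(fc["hist_Variance"]), 0)
  expect_equal(unname(fc["hist_Entropy"]), 0)
  expect_equal(unname(fc["hist_Mode"]), 2.5)
  set.seed(26)
  fn <- histogram_features(rnorm(1000))
  expect_lt(abs(fn["hist_Skewness"]), 0.25)
  expect_error(histogram_features(numeric(0)), "empty")
})

test_that("shape features behave like their geometric definitions", {
  # rasterised disk: sphericity ~ 1
  n <- 64
  rr <- matrix(seq_len(n), n, n) - 32.5
  cc <- t(rr)
  disk <- (rr^2 + cc^2 <= 20^2) * 1
  f <- shape_features(disk, spacing = 1)
  expect_lt(abs(f["shape_Sphericity"] - 1), 0.03)
  expect_equal(unname(f["shape_Elongation"]), 1, tolerance = 0.02)
  # 2:1 ellipse: elongation ~ 0.5
  ell <- ((rr / 28)^2 + (cc / 14)^2 <= 1) * 1
  fe <- shape_features(ell, spacing = 1)
  expect_equal(unname(fe["shape_Elongation"]), 0.5, tolerance = 0.025)
  # scaling by 2 doubles diameters, leaves elongation unchanged
  n2 <- 128
  rr2 <- matrix(seq_len(n2), n2, n2) - 64.5
  cc2 <- t(rr2)
  ell2 <- ((rr2 / 56)^2 + (cc2 / 28)^2 <= 1) * 1
  f2 <- shape_features(ell2, spacing = 1)
  expect_equal(unname(f2["shape_MajorAxisLength"]),
               2 * unname(fe["shape_MajorAxisLength"]), tolerance = 0.02)
  expect_equal(unname(f2["shape_Elongation"]), unname(fe["shape_Elongation"]),
               tolerance = 0.02)
  expect_error(shape_features(matrix(0, 4, 4)), "empty")
})

test_that("first-order statistics hit their closed forms", {
  fc <- first_order_features(rep(3, 25))
  expect_equal(unname(fc["fo_Mean"]), 3)
  expect_equal(unname(fc["fo_Median"]), 3)
  expect_equal(unname(fc["fo_RootMeanSquared"]), 3)
  expect_equal(unname(fc["fo_Variance"]), 0)
  fpm <- first_order_features(c(rep(-1, 50), rep(1, 50)))
  expect_equal(unname(fpm["fo_RootMeanSquared"]), 1)
  expect_equal(unname(fpm["fo_Mean"]), 0)
  expect_equal(length(fpm), 18L)
})

test_that("extraction is deterministic and catalogue-ordered", {
  p <- generate_phantom(tiny_phantom_config(seed = 27L), 6)
  v1 <- extract_all(p)
  v2 <- extract_all(p)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_catalogue()$name)
  expect_true(all(is.finite(v1)))
  m <- extract_cohort(list(p, p))
  expect_equal(dim(m), c(2L, 868L))
  expect_equal(m[1, ], m[2, ])
})
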
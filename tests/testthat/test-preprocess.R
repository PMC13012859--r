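test_that("resample honours spacing, extent and interpolation contracts", {
  img <- matrix(rnorm(256 * 256), 256, 256)
  expect_identical(resample(img, 0.5, 0.5), img)
  out <- resample(img, 0.5, 1.0)
  expect_equal(dim(out), c(128L, 128L))
  const <- matrix(3.7, 64, 64)
  expect_equal(resample(const, 1, 0.7), matrix(3.7, 91, 91), tolerance = 1e-12)
  expect_error(resample(img, 0, 1), "positive")
  expect_error(resample(img, 1, -2), "positive")
  # nearest-neighbour keeps masks binary
  msk <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  rs <- resample(msk, 1, 0.6, method = "nearest")
  expect_true(all(rs %in% c(0, 1)))
})

test_that("zscore standardizes to zero mean, unit SD and is idempotent", {
  set.seed(1)
  img <- matrix(rnorm(900, 5, 3), 30, 30)
  z <- zscore(img)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(stats::sd(z) - 1), 1e-6)
  expect_equal(zscore(z), z, tolerance = 1e-10)
  checker <- matrix(c(0, 1), 10, 10)
  zc <- sort(unique(as.vector(round(zscore(checker), 10))))
  expect_equal(length(zc), 2L)
  expect_equal(zc[1], -zc[2])
  expect_error(zscore(matrix(2, 5, 5)), "constant")
})

test_that("augment applies one geometric transform to image and mask alike", {
  cfg_off <- augmentation_config(rotation_limit = 0, flip_horizontal = FALSE,
                                 flip_vertical = FALSE, scale_range = c(1, 1),
                                 gaussian_noise_sd = 0)
  p <- generate_phantom(tiny_phantom_config(seed = 2L), 4)
  out <- augment(p, cfg_off)
  expect_identical(out$image, p$image)
  expect_identical(out$mask, p$mask)

  # horizontal flip only: applying the same draw twice restores the input
  cfg_flip <- augmentation_config(rotation_limit = 0, flip_horizontal = TRUE,
                                  flip_vertical = FALSE,
                                  scale_range = c(1, 1),
                                  gaussian_noise_sd = 0)
  set.seed(10); once <- augment(p, cfg_flip)
  set.seed(10); twice <- augment(once, cfg_flip)
  expect_equal(twice$image, p$image, tolerance = 1e-12)
  expect_identical(twice$mask, p$mask)

  # rotation preserves mask area within interpolation tolerance
  cfg_rot <- augmentation_config(rotation_limit = 15, flip_horizontal = FALSE,
                                 flip_vertical = FALSE, scale_range = c(1, 1),
                                 gaussian_noise_sd = 0)
  set.seed(3)
  rot <- augment(p, cfg_rot)
  expect_true(all(rot$mask %in% c(0L, 1L)))
  expect_lt(abs(sum(rot$mask) - sum(p$mask)) / sum(p$mask), 0.02)
})

test_that("split_cohort reproduces the floor rule and partitions exactly", {
  sp <- split_cohort(seq_len(141), split_spec(seed = 1))
  expect_equal(lengths(sp), c(train = 99L, validation = 21L, test = 21L))
  expect_setequal(unlist(sp), seq_len(141))

  sp100 <- split_cohort(seq_len(100), split_spec(seed = 2))
  expect_equal(lengths(sp100), c(train = 70L, validation = 15L, test = 15L))

  all_train <- split_cohort(seq_len(10), split_spec(c(1, 0, 0)))
  expect_equal(lengths(all_train), c(train = 10L, validation = 0L, test = 0L))

  for (n in c(1, 7, 53, 200)) {
    sp_n <- split_cohort(seq_len(n), split_spec(seed = n))
    expect_equal(sum(lengths(sp_n)), n)
    expect_equal(anyDuplicated(unlist(sp_n)), 0L)
  }
  expect_error(split_cohort(c(1, 1, 2), split_spec()), "duplicate")
  expect_error(split_cohort(integer(0), split_spec()), "non-empty")
})
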
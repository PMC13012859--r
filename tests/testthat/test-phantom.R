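test_that("pathology label encoding is bijective and matches the category table", {
  expect_equal(pathology_label(0, 0, 0)$category, 0L)
  expect_equal(pathology_label(0, 0, 0)$name,
               "Small-cell keratinizing squamous cell carcinoma")
  expect_equal(pathology_label(1, 1, 0)$category, 6L)
  expect_equal(pathology_label(1, 1, 0)$name,
               "Large-cell non-keratinizing squamous cell carcinoma")
  cats <- c()
  for (cs in 0:1) for (ke in 0:1) for (hi in 0:1) {
    cats <- c(cats, pathology_label(cs, ke, hi)$category)
  }
  expect_setequal(cats, 0:7)
  for (k in 0:7) {
    expect_equal(pathology_label_from_category(k)$category, k)
  }
  expect_error(pathology_label(2, 0, 0), "binary")
})

test_that("phantom generation is deterministic given the seed", {
  cfg <- tiny_phantom_config(seed = 42L)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$clinical, b$clinical)
})

test_that("noiseless phantoms separate lesion from background exactly", {
  cfg <- tiny_phantom_config(seed = 7L, noise_sd = 0)
  for (cat in c(0, 4, 7)) {
    p <- generate_phantom(cfg, cat)
    expect_gt(min(p$image[p$mask == 1]), max(p$image[p$mask == 0]))
    # threshold segmentation recovers the mask exactly
    thr <- (min(p$image[p$mask == 1]) + max(p$image[p$mask == 0])) / 2
    expect_identical((p$image > thr) * 1L, p$mask)
  }
})

test_that("masks are single 4-connected components with in-range diameters", {
  cfg <- tiny_phantom_config(seed = 3L)
  ds <- numeric(0)
  for (i in 1:200) {
    p <- generate_phantom(cfg, i %% 8, index = i)
    d <- equivalent_diameter(p$mask, p$spacing)
    ds <- c(ds, d)
    if (i <= 25) {
      lab <- crfeseg:::label_components(p$mask == 1, connectivity = 4L)
      expect_equal(max(lab), 1L)
    }
  }
  expect_gte(min(ds), 10)
  expect_lte(max(ds), 40)
})

test_that("cohort labels follow the requested class distribution", {
  cfg <- tiny_phantom_config(seed = 5L)
  co <- generate_cohort(cfg, 100, c(0, 0, 0, 0, 0, 0, 1, 0))
  expect_true(all(vapply(co, function(p) p$label$category, numeric(1)) == 6))

  # multinomial counts within 3 SD for a uniform {4,6,7} draw; labels only
  set.seed(cfg$seed)
  cats <- sample(0:7, 10000, replace = TRUE,
                 prob = c(0, 0, 0, 0, 1, 0, 1, 1) / 3)
  for (k in c(4, 6, 7)) {
    expect_lt(abs(sum(cats == k) - 10000 / 3),
              3 * sqrt(10000 * (1 / 3) * (2 / 3)))
  }
  expect_error(generate_cohort(cfg, 0), "n must be")
  expect_error(generate_cohort(cfg, 10, rep(-1 / 8, 8)), "non-negative")
})

test_that("lesion mean intensity separates distant categories", {
  cfg <- tiny_phantom_config(seed = 9L)
  n_each <- 250
  stats0 <- vapply(seq_len(n_each), function(i) {
    p <- generate_phantom(cfg, 0, index = i)
    mean(p$image[p$mask == 1])
  }, numeric(1))
  stats7 <- vapply(seq_len(n_each), function(i) {
    p <- generate_phantom(cfg, 7, index = n_each + i)
    mean(p$image[p$mask == 1])
  }, numeric(1))
  thr <- (mean(stats0) + mean(stats7)) / 2
  acc <- (sum(stats0 < thr) + sum(stats7 >= thr)) / (2 * n_each)
  expect_gt(acc, 0.9)
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(image_size = 32L), "image_size")
  expect_error(phantom_config(lesion_diameter_range = c(40, 10)), "interval")
  expect_error(phantom_config(image_size = 64L, pixel_spacing = 0.5,
                              lesion_diameter_range = c(10, 40)),
               "interval")   # 40 mm does not fit a 32 mm field
  expect_error(phantom_config(noise_sd = -1))
})
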
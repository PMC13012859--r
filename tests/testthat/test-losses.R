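test_that("dice loss hits its analytic anchor points", {
  y <- matrix(0, 20, 20); y[5:14, 5:14] <- 1          # 100 lesion pixels
  expect_lt(dice_loss(y, y), 1e-6)
  disj <- matrix(0, 20, 20); disj[15:19, 1:20] <- 1   # 100 px, disjoint
  expect_gt(dice_loss(disj, y), 1 - 1e-6)
  half <- matrix(0, 20, 20); half[5:14, 5:9] <- 1; half[15:19, 1:10] <- 1
  # |X∩Y| = 50, |X| = |Y| = 100
  expect_equal(dice_loss(half, y, epsilon = 1e-12), 0.5, tolerance = 1e-9)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("cross-entropy matches its closed form and a per-pixel oracle", {
  y <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(cross_entropy_loss(y, y), 1e-5)
  expect_equal(cross_entropy_loss(matrix(0.5), matrix(1)), log(2),
               tolerance = 1e-12)
  set.seed(4)
  p <- matrix(runif(64), 8, 8)
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  oracle <- 0
  for (i in 1:8) for (j in 1:8) {
    oracle <- oracle - (t[i, j] * log(p[i, j]) +
                          (1 - t[i, j]) * log(1 - p[i, j]))
  }
  expect_equal(cross_entropy_loss(p, t), oracle / 64, tolerance = 1e-12)
})

test_that("size prior penalises only out-of-range equivalent diameters", {
  lc <- loss_config(pixel_spacing = 1)
  mk_pred <- function(d_mm) {
    v <- numeric(6400)
    v[seq_len(floor(pi * (d_mm / 2)^2))] <- 1   # soft count just under d_mm
    matrix(v, 80, 80)
  }
  expect_equal(size_prior_loss(mk_pred(25), lc), 0)
  expect_equal(size_prior_loss(matrix(0, 80, 80), lc), (10 / 30)^2,
               tolerance = 1e-12)
  d40 <- 2 * sqrt(sum(mk_pred(40)) / pi)
  expect_lt(abs(d40 - 40), 0.1)
  expect_lte(d40, 40)
  expect_equal(size_prior_loss(mk_pred(40), lc), 0)
  # ground-truth phantom masks never incur a size penalty
  p <- generate_phantom(tiny_phantom_config(seed = 6L), 2)
  expect_equal(size_prior_loss(p$mask, lc), 0)
})

test_that("total loss is the module sum plus weighted global terms", {
  lc <- loss_config(lambda_global = 2)
  expect_equal(total_loss(0.5, numeric(0), 0, loss_config()), 0.5)
  expect_equal(total_loss(c(0.2, 0.3), 0.1, 0.05, lc), 0.75)
  lc0 <- loss_config(lambda_global = 0)
  expect_equal(total_loss(c(0.2, 0.3), 99, 0.05, lc0), 0.55)
  # linear in lambda
  lam <- c(0, 0.5, 1, 2, 4)
  vals <- vapply(lam, function(l) {
    total_loss(0.1, c(0.2, 0.3), 0.05, loss_config(lambda_global = l))
  }, numeric(1))
  expect_equal(diff(vals) / diff(lam), rep(0.5, 4), tolerance = 1e-12)
})

test_that("cosine schedule is exact at the endpoints and midpoint", {
  sc <- schedule_config(eta_min = 0, eta_max = 0.001, T_i = 100)
  expect_equal(cosine_lr(0, sc), 0.001)
  expect_equal(cosine_lr(100, sc), 0)
  expect_equal(cosine_lr(50, sc), 0.0005)
  sc2 <- schedule_config(eta_min = 1e-5, eta_max = 0.001, T_i = 77)
  expect_equal(cosine_lr(0, sc2), 0.001)
  expect_equal(cosine_lr(77, sc2), 1e-5)
  expect_equal(cosine_lr(77 / 2, sc2), (0.001 + 1e-5) / 2)
  lrs <- vapply(0:77, cosine_lr, numeric(1), config = sc2)
  expect_true(all(diff(lrs) <= 1e-15))
  expect_error(cosine_lr(78, sc2), "T_cur")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(8)
  p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  t <- matrix(rbinom(36, 1, 0.4), 6, 6)
  lc <- loss_config(pixel_spacing = 4)   # force out-of-range diameter
  for (fun in list(
    list(f = function(x) dice_loss(x, t),
         g = function(x) crfeseg:::dice_loss_grad(x, t)),
    list(f = function(x) cross_entropy_loss(x, t),
         g = function(x) crfeseg:::cross_entropy_loss_grad(x, t)),
    list(f = function(x) size_prior_loss(x, lc),
         g = function(x) crfeseg:::size_prior_loss_grad(x, lc)))) {
    g <- fun$g(p)
    for (idx in c(1, 17, 36)) {
      eps <- 1e-6
      pp <- p; pp[idx] <- pp[idx] + eps
      pm <- p; pm[idx] <- pm[idx] - eps
      expect_equal(g[idx], (fun$f(pp) - fun$f(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
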
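tiny_spec <- function(alpha = 0) {
  crfe_model_spec(input_size = 16L, encoder_channels = c(2L, 3L, 4L),
                  recurrent_units = 5L, decoder_channels = c(3L, 2L),
                  attention_alpha_init = alpha)
}

test_that("activation primitives obey their definitions", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(5), 5)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 2)), c(0, 2))
  expect_equal(sigmoid(0), 0.5)
  for (x in c(-3, -0.5, 0.7, 10)) {
    expect_equal(sigmoid(x) + sigmoid(-x), 1, tolerance = 1e-12)
  }
})

test_that("encoder produces the documented pyramid shapes", {
  m64 <- crfe_init(crfe_model_spec(input_size = 64L,
                                   encoder_channels = c(8L, 16L, 32L),
                                   recurrent_units = 8L,
                                   decoder_channels = c(16L, 8L)), seed = 1)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  enc <- crfe_encode(m64, x)
  expect_equal(dim(enc$e1), c(64L, 64L, 8L, 1L))
  expect_equal(dim(enc$e2), c(32L, 32L, 16L, 1L))
  expect_equal(dim(enc$e3), c(16L, 16L, 32L, 1L))
  expect_equal(dim(enc$deepest), c(8L, 8L, 32L, 1L))
  expect_error(crfe_model_spec(input_size = 250L), "divisible")
  expect_error(crfe_encode(m64, array(0, c(60, 60, 1, 1))), "divisible")
})

test_that("recurrent context preserves shape and is zero at zero", {
  set.seed(2)
  U <- 5L; C <- 4L
  params <- list(
    lstm_f = list(Wx = matrix(0, C, 4 * U), Wh = matrix(0, U, 4 * U),
                  b = numeric(4 * U)),
    lstm_b = list(Wx = matrix(0, C, 4 * U), Wh = matrix(0, U, 4 * U),
                  b = numeric(4 * U)),
    proj = list(W = matrix(0, U, C), b = numeric(C)))
  z <- array(0, c(4, 4, C, 1))
  expect_equal(recurrent_context(z, params), z)

  rnd <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.3), nr, nc)
  params_r <- list(lstm_f = list(Wx = rnd(C, 4 * U), Wh = rnd(U, 4 * U),
                                 b = rnorm(4 * U, 0, 0.1)),
                   lstm_b = list(Wx = rnd(C, 4 * U), Wh = rnd(U, 4 * U),
                                 b = rnorm(4 * U, 0, 0.1)),
                   proj = list(W = rnd(U, C), b = rnorm(C, 0, 0.1)))
  fm <- array(rnorm(4 * 4 * C * 2), c(4, 4, C, 2))
  out <- recurrent_context(fm, params_r)
  expect_equal(dim(out), dim(fm))

  # bidirectionality: reversing the serialised sequence and swapping the
  # forward/backward parameter sets yields the reversed fused output
  swapped <- params_r
  swapped$lstm_f <- params_r$lstm_b
  swapped$lstm_b <- params_r$lstm_f
  X <- crfeseg:::serialize_rowmajor(fm)
  fm_rev <- crfeseg:::deserialize_rowmajor(rev(X), 4, 4)
  out_rev <- recurrent_context(fm_rev, swapped)
  Yr <- crfeseg:::serialize_rowmajor(out_rev)
  back <- crfeseg:::deserialize_rowmajor(rev(Yr), 4, 4)
  expect_equal(back, out, tolerance = 1e-12)
})

test_that("position attention is the identity at alpha 0 and row-stochastic", {
  set.seed(3)
  C <- 3L
  A <- array(rnorm(2 * 2 * C), c(2, 2, C))
  W1 <- matrix(rnorm(C * C), C, C); W2 <- matrix(rnorm(C * C), C, C)
  W3 <- matrix(rnorm(C * C), C, C)
  expect_equal(position_attention(A, W1, W2, W3, alpha = 0), A)

  # constant feature block: every attention row is uniform 1/N
  Ac <- array(1.3, c(2, 2, C))
  out <- position_attention(Ac, W1, W2, W3, alpha = 0.5, return_map = TRUE)
  S <- attr(out, "S")[[1]]
  expect_equal(S, matrix(1 / 4, 4, 4), tolerance = 1e-12)

  out2 <- position_attention(A, W1, W2, W3, alpha = 0.8, return_map = TRUE)
  S2 <- attr(out2, "S")[[1]]
  expect_equal(rowSums(S2), rep(1, 4), tolerance = 1e-10)
  expect_true(all(S2 >= 0))
})

test_that("attention equals the brute-force double-loop oracle", {
  set.seed(4)
  for (rep in 1:5) {
    H <- sample(2:4, 1); W <- sample(2:4, 1); C <- sample(2:4, 1)
    A <- array(rnorm(H * W * C), c(H, W, C))
    Wb <- matrix(rnorm(C * C, 0, 0.5), C, C)
    Wc <- matrix(rnorm(C * C, 0, 0.5), C, C)
    Wd <- matrix(rnorm(C * C, 0, 0.5), C, C)
    alpha <- runif(1, -1, 1)
    ours <- position_attention(A, Wb, Wc, Wd, alpha, return_map = TRUE)
    orc <- oracle_attention(A, Wb, Wc, Wd, alpha)
    expect_equal(array(ours, dim(A)), orc$E, tolerance = 1e-10)
    expect_equal(attr(ours, "S")[[1]], orc$S, tolerance = 1e-10)
  }
})

test_that("full forward pass keeps shape, range and determinism", {
  m <- crfe_init(crfe_model_spec(input_size = 64L,
                                 encoder_channels = c(4L, 6L, 8L),
                                 recurrent_units = 6L,
                                 decoder_channels = c(6L, 4L)), seed = 5)
  img <- matrix(rnorm(64 * 64), 64, 64)
  out1 <- crfe_forward(m, img)
  out2 <- crfe_forward(m, img)
  expect_equal(dim(out1$prob), c(64L, 64L, 1L, 1L))
  expect_true(all(out1$prob > 0 & out1$prob < 1))
  expect_identical(out1$prob, out2$prob)
  # decode contract: probability map from context + skips
  enc <- crfe_encode(m, array(img, c(64, 64, 1, 1)))
  ctx <- position_attention(recurrent_context(enc$deepest, m),
                            m$params$att$Wb, m$params$att$Wc,
                            m$params$att$Wd, m$params$att$alpha)
  dec <- crfe_decode(m, ctx, enc)
  expect_equal(dec, out1$prob, tolerance = 1e-12)
})

test_that("backpropagation matches central-difference gradients", {
  set.seed(6)
  m <- crfe_init(tiny_spec(alpha = 0.4), seed = 7)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  masks <- list(matrix(rbinom(256, 1, 0.3), 16, 16),
                matrix(rbinom(256, 1, 0.3), 16, 16))
  lcfg <- loss_config(pixel_spacing = 1)
  fw <- crfe_forward(m, x, with_cache = TRUE)
  lg <- crfeseg:::batch_loss_and_grads(fw$prob, fw$aux_prob, masks, lcfg)
  gr <- crfeseg:::crfe_backward(m, fw$cache, lg$dprob, lg$daux)
  lossfun <- function(mm) {
    f <- crfe_forward(mm, x)
    crfeseg:::batch_loss_and_grads(f$prob, f$aux_prob, masks, lcfg)$loss
  }
  eps <- 1e-5
  picks <- list(c("enc1", "W", 3), c("enc2", "W", 10), c("enc3", "b", 2),
                c("lstm_f", "Wx", 4), c("lstm_b", "Wh", 7), c("proj", "W", 2),
                c("att", "Wb", 3), c("att", "Wc", 5), c("att", "Wd", 2),
                c("att", "alpha", 1), c("dec1", "W", 20), c("dec2", "W", 11),
                c("out", "W", 2), c("aux", "W", 1))
  for (p in picks) {
    nm <- p[1]; fn <- p[2]; i <- as.integer(p[3])
    mm <- m
    v0 <- mm$params[[nm]][[fn]][i]
    mm$params[[nm]][[fn]][i] <- v0 + eps; lp <- lossfun(mm)
    mm$params[[nm]][[fn]][i] <- v0 - eps; lm <- lossfun(mm)
    num <- (lp - lm) / (2 * eps)
    ana <- gr[[nm]][[fn]][i]
    expect_equal(ana, num, tolerance = 1e-3,
                 label = paste("grad", nm, fn, i))
  }
})
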
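#' CRFE segmentation model specification
#'
#' The CRFE (convolutional recurrent feature extraction) architecture is a
#' U-shaped encoder/decoder: three 3x3 convolution blocks (default 32/64/128
#' channels) with 2x2 max pooling, a bidirectional LSTM context module
#' (default 256 units) applied to the row-major serialisation of the deepest
#' feature map, a position-attention module whose learnable mixing scalar
#' alpha starts at 0 (so the module is the identity at initialisation), and
#' a decoder with 2x2 bilinear upsampling, 3x3 convolutions (64 then 32
#' channels), channel-concatenation skip connections from the encoder, a
#' final 1x1 convolution and a sigmoid head. An auxiliary 1x1 sigmoid head
#' at the deepest scale provides deep supervision.
#'
#' @param input_size square input side in pixels; must be divisible by 8
#'   (three 2x2 pooling stages). Default 256.
#' @param encoder_channels three positive integers, default `c(32, 64, 128)`.
#' @param recurrent_units LSTM hidden units per direction, default 256.
#' @param decoder_channels two positive integers, default `c(64, 32)`.
#' @param attention_alpha_init initial value of the attention scalar,
#'   default 0.
#' @return object of class `crfe_model_spec`.
#' @export
crfe_model_spec <- function(input_size = 256L,
                            encoder_channels = c(32L, 64L, 128L),
                            recurrent_units = 256L,
                            decoder_channels = c(64L, 32L),
                            attention_alpha_init = 0) {
  stopifnot(length(encoder_channels) == 3L, all(encoder_channels > 0),
            length(decoder_channels) == 2L, all(decoder_channels > 0),
            recurrent_units > 0, is.finite(attention_alpha_init))
  if (input_size %% 8L != 0L) {
    stop("input_size must be divisible by 8 (three 2x2 pooling stages)")
  }
  structure(list(input_size = as.integer(input_size),
                 encoder_channels = as.integer(encoder_channels),
                 recurrent_units = as.integer(recurrent_units),
                 decoder_channels = as.integer(decoder_channels),
                 attention_alpha_init = attention_alpha_init),
            class = "crfe_model_spec")
}

#' Initialise CRFE parameters
#'
#' He-scaled Gaussian initialisation for convolutions, uniform
#' `+/- 1/sqrt(units)` for the recurrent weights, and alpha at its
#' configured initial value (0 by default, making the attention module an
#' identity map at the start of training).
#'
#' @param spec a [crfe_model_spec()].
#' @param seed integer seed.
#' @return object of class `crfe_model`: list with `spec` and `params`.
#' @export
crfe_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "crfe_model_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  C <- spec$encoder_channels; D <- spec$decoder_channels
  U <- spec$recurrent_units
  he <- function(fan_in, cout) {
    matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  }
  uni <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  k <- 1 / sqrt(U)
  params <- list(
    enc1 = list(W = he(9L, C[1]), b = numeric(C[1])),
    enc2 = list(W = he(9L * C[1], C[2]), b = numeric(C[2])),
    enc3 = list(W = he(9L * C[2], C[3]), b = numeric(C[3])),
    lstm_f = list(Wx = uni(C[3], 4L * U, k), Wh = uni(U, 4L * U, k),
                  b = numeric(4L * U)),
    lstm_b = list(Wx = uni(C[3], 4L * U, k), Wh = uni(U, 4L * U, k),
                  b = numeric(4L * U)),
    proj = list(W = uni(U, C[3], k), b = numeric(C[3])),
    att = list(Wb = he(C[3], C[3]) / 3, Wc = he(C[3], C[3]) / 3,
               Wd = he(C[3], C[3]) / 3, alpha = spec$attention_alpha_init),
    dec1 = list(W = he(9L * (C[3] + C[3]), D[1]), b = numeric(D[1])),
    dec2 = list(W = he(9L * (D[1] + C[2]), D[2]), b = numeric(D[2])),
    out = list(W = he(D[2] + C[1], 1L), b = 0),
    aux = list(W = he(C[3], 1L), b = 0)
  )
  structure(list(spec = spec, params = params), class = "crfe_model")
}

#' Encoder: multi-scale feature pyramid
#'
#' Three conv3x3+ReLU blocks, each followed by 2x2 max pooling. Returns the
#' pre-pool activations (retained for skip connections) and the pooled
#' deepest block.
#'
#' @param model a `crfe_model`.
#' @param x input array `(H, W, 1, B)` with H = W divisible by 8.
#' @return list with `e1`, `e2`, `e3` (pre-pool pyramid) and `deepest`
#'   (pooled, `H/8 x W/8 x C3`).
#' @export
crfe_encode <- function(model, x) {
  fw <- crfe_encode_cached(model$params, x)
  fw[c("e1", "e2", "e3", "deepest")]
}

crfe_encode_cached <- function(params, x) {
  d <- dim(x)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
    stop("input side must be divisible by 8")
  }
  c1 <- conv3_forward(x, params$enc1$W, params$enc1$b)
  r1 <- relu_forward(c1$out)
  p1 <- maxpool_forward(r1$out)
  c2 <- conv3_forward(p1$out, params$enc2$W, params$enc2$b)
  r2 <- relu_forward(c2$out)
  p2 <- maxpool_forward(r2$out)
  c3 <- conv3_forward(p2$out, params$enc3$W, params$enc3$b)
  r3 <- relu_forward(c3$out)
  p3 <- maxpool_forward(r3$out)
  list(e1 = r1$out, e2 = r2$out, e3 = r3$out, deepest = p3$out,
       c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
       c3 = c3, r3 = r3, p3 = p3)
}

#' Bidirectional recurrent context module
#'
#' The deepest feature block is serialised row-major (each spatial position
#' contributes its channel vector as one sequence element), processed by
#' forward and backward LSTM passes, the two hidden sequences are fused by
#' elementwise sum, projected back to the input channel count and reshaped
#' to the input spatial shape.
#'
#' @param features array `(H, W, C, B)` (a lone `(H, W, C)` block is
#'   treated as batch size 1).
#' @param params list with `lstm_f`, `lstm_b` (each `Wx`, `Wh`, `b`) and
#'   `proj` (`W`, `b`); taken from a `crfe_model` if one is supplied.
#' @return feature block of the same shape as `features`.
#' @export
recurrent_context <- function(features, params) {
  if (inherits(params, "crfe_model")) params <- params$params
  if (length(dim(features)) == 3L) {
    dim(features) <- c(dim(features), 1L)
  }
  recurrent_context_cached(features, params)$out
}

recurrent_context_cached <- function(fm, params) {
  d <- dim(fm); H <- d[1]; W <- d[2]
  X <- serialize_rowmajor(fm)
  N <- length(X)
  fwd <- lstm_forward(X, params$lstm_f)
  bwd <- lstm_forward(rev(X), params$lstm_b)
  hb_aligned <- rev(bwd$H)
  Y <- vector("list", N)
  for (t in seq_len(N)) {
    hs <- fwd$H[[t]] + hb_aligned[[t]]
    Y[[t]] <- sweep(hs %*% params$proj$W, 2L, params$proj$b, "+")
  }
  out <- deserialize_rowmajor(Y, H, W)
  list(out = out,
       cache = list(X = X, fwd = fwd, bwd = bwd, H = H, W = W, dims = d))
}

recurrent_context_backward <- function(dout, cache, params) {
  H <- cache$H; W <- cache$W
  dY <- serialize_rowmajor(dout)
  N <- length(dY)
  U <- nrow(params$proj$W)
  dWp <- matrix(0, U, ncol(params$proj$W)); dbp <- numeric(ncol(params$proj$W))
  dHf <- vector("list", N); dHb_aligned <- vector("list", N)
  hb_aligned <- rev(cache$bwd$H)
  for (t in seq_len(N)) {
    hs <- cache$fwd$H[[t]] + hb_aligned[[t]]
    dWp <- dWp + crossprod(hs, dY[[t]])
    dbp <- dbp + colSums(dY[[t]])
    dhs <- dY[[t]] %*% t(params$proj$W)
    dHf[[t]] <- dhs
    dHb_aligned[[t]] <- dhs
  }
  bf <- lstm_backward(dHf, cache$fwd$cache, params$lstm_f)
  bb <- lstm_backward(rev(dHb_aligned), cache$bwd$cache, params$lstm_b)
  dXb <- rev(bb$dX)
  dX <- vector("list", N)
  for (t in seq_len(N)) dX[[t]] <- bf$dX[[t]] + dXb[[t]]
  dfm <- deserialize_rowmajor(dX, H, W)
  list(dx = dfm,
       grads = list(lstm_f = list(Wx = bf$dWx, Wh = bf$dWh, b = bf$db),
                    lstm_b = list(Wx = bb$dWx, Wh = bb$dWh, b = bb$db),
                    proj = list(W = dWp, b = dbp)))
}

#' Position attention over a feature block
#'
#' Learned 1x1 projections produce query/key/value maps B, C, D from the
#' input A; pairwise similarity scores `B_i . C_j` are softmax-normalised
#' over i to give an N x N spatial attention map S (N = H*W positions, each
#' row summing to 1), and the output is
#' `E_j = alpha * sum_i S[j,i] * D_i + A_j`. With `alpha = 0` the module is
#' exactly the identity.
#'
#' @param A feature block `(H, W, C)` or `(H, W, C, B)`.
#' @param Wb,Wc,Wd `C x C` projection matrices.
#' @param alpha mixing scalar.
#' @param return_map if TRUE attach the attention map(s) S as attribute
#'   `"S"` (list per batch element).
#' @return feature block shaped like `A`.
#' @export
position_attention <- function(A, Wb, Wc, Wd, alpha, return_map = FALSE) {
  drop3 <- FALSE
  if (length(dim(A)) == 3L) { dim(A) <- c(dim(A), 1L); drop3 <- TRUE }
  fw <- attention_forward(A, list(Wb = Wb, Wc = Wc, Wd = Wd, alpha = alpha))
  out <- fw$out
  if (!all(is.finite(out))) stop("non-finite activations in attention")
  if (return_map) attr(out, "S") <- lapply(fw$cache$per, function(p) p$S)
  if (drop3) {
    S <- attr(out, "S")
    dim(out) <- dim(out)[1:3]
    if (return_map) attr(out, "S") <- S
  }
  out
}

attention_forward <- function(fm, params) {
  d <- dim(fm); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  N <- H * W
  out <- array(0, d)
  per <- vector("list", B)
  for (bi in seq_len(B)) {
    Am <- t(matrix(fm[, , , bi], N, C))            # C x N, column-major pos
    Bm <- params$Wb %*% Am
    Cm <- params$Wc %*% Am
    Dm <- params$Wd %*% Am
    M <- crossprod(Bm, Cm)                         # M[i,j] = b_i . c_j
    Ms <- sweep(M, 2L, apply(M, 2, max), "-")
    E <- exp(Ms)
    Scol <- sweep(E, 2L, colSums(E), "/")          # softmax over i, per j
    S <- t(Scol)                                   # S[j,i], rows sum to 1
    ctx <- Dm %*% t(S)                             # C x N
    Em <- params$alpha * ctx + Am
    out[, , , bi] <- array(t(Em), c(H, W, C))
    per[[bi]] <- list(Am = Am, Bm = Bm, Cm = Cm, Dm = Dm,
                      Scol = Scol, S = S, ctx = ctx)
  }
  list(out = out, cache = list(per = per, dims = d))
}

attention_backward <- function(dout, cache, params) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  N <- H * W
  dWb <- matrix(0, C, C); dWc <- matrix(0, C, C); dWd <- matrix(0, C, C)
  dalpha <- 0
  dx <- array(0, d)
  for (bi in seq_len(B)) {
    p <- cache$per[[bi]]
    dEm <- t(matrix(dout[, , , bi], N, C))         # C x N
    dAm <- dEm
    dalpha <- dalpha + sum(dEm * p$ctx)
    dctx <- params$alpha * dEm
    dDm <- dctx %*% p$S
    dtS <- crossprod(p$Dm, dctx)                   # N x N, gradient on t(S)
    dScol <- dtS                                   # t(S)[i,j] = Scol[i,j]
    sums <- colSums(dScol * p$Scol)
    dM <- p$Scol * sweep(dScol, 2L, sums, "-")
    dBm <- p$Cm %*% t(dM)
    dCm <- p$Bm %*% dM
    dAm <- dAm + t(params$Wb) %*% dBm + t(params$Wc) %*% dCm +
      t(params$Wd) %*% dDm
    dWb <- dWb + dBm %*% t(p$Am)
    dWc <- dWc + dCm %*% t(p$Am)
    dWd <- dWd + dDm %*% t(p$Am)
    dx[, , , bi] <- array(t(dAm), c(H, W, C))
  }
  list(dx = dx, dWb = dWb, dWc = dWc, dWd = dWd, dalpha = dalpha)
}

#' Full CRFE forward pass
#'
#' @param model a `crfe_model`.
#' @param x input array `(H, W, 1, B)`; a single `(H, W)` image or
#'   `(H, W, 1)` block is promoted to batch size 1.
#' @param with_cache keep layer caches for backpropagation.
#' @return list with `prob` (main sigmoid head, same spatial size as input),
#'   `aux_prob` (deepest-scale auxiliary head), and `cache` when requested.
#' @export
crfe_forward <- function(model, x, with_cache = FALSE) {
  stopifnot(inherits(model, "crfe_model"))
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  params <- model$params
  enc <- crfe_encode_cached(params, x)
  rc <- recurrent_context_cached(enc$deepest, params)
  at <- attention_forward(rc$out, params$att)
  auxc <- conv1_forward(at$out, params$aux$W, params$aux$b)
  aux_prob <- sigmoid(auxc$out)
  u1 <- upsample2_forward(at$out)
  cat1 <- concat_channels(u1$out, enc$e3)
  dc1 <- conv3_forward(cat1, params$dec1$W, params$dec1$b)
  dr1 <- relu_forward(dc1$out)
  u2 <- upsample2_forward(dr1$out)
  cat2 <- concat_channels(u2$out, enc$e2)
  dc2 <- conv3_forward(cat2, params$dec2$W, params$dec2$b)
  dr2 <- relu_forward(dc2$out)
  u3 <- upsample2_forward(dr2$out)
  cat3 <- concat_channels(u3$out, enc$e1)
  oc <- conv1_forward(cat3, params$out$W, params$out$b)
  prob <- sigmoid(oc$out)
  res <- list(prob = prob, aux_prob = aux_prob)
  if (with_cache) {
    res$cache <- list(enc = enc, rc = rc, at = at, auxc = auxc,
                      u1 = u1, dc1 = dc1, dr1 = dr1,
                      u2 = u2, dc2 = dc2, dr2 = dr2,
                      u3 = u3, oc = oc, prob = prob, aux_prob = aux_prob,
                      c3ch = dim(at$out)[3])
  }
  res
}

#' Decoder: probability map from context features and encoder skips
#'
#' @param model a `crfe_model`.
#' @param context deepest-scale feature block (after recurrent context and
#'   attention), `(H/8, W/8, C3, B)`.
#' @param skips list with `e1`, `e2`, `e3` from [crfe_encode()].
#' @return probability array `(H, W, 1, B)` with values in (0, 1).
#' @export
crfe_decode <- function(model, context, skips) {
  params <- model$params
  u1 <- upsample2_forward(context)
  dc1 <- conv3_forward(concat_channels(u1$out, skips$e3),
                       params$dec1$W, params$dec1$b)
  u2 <- upsample2_forward(relu(dc1$out))
  dc2 <- conv3_forward(concat_channels(u2$out, skips$e2),
                       params$dec2$W, params$dec2$b)
  u3 <- upsample2_forward(relu(dc2$out))
  oc <- conv1_forward(concat_channels(u3$out, skips$e1),
                      params$out$W, params$out$b)
  sigmoid(oc$out)
}

# Full backward pass: dprob / daux_prob are gradients w.r.t. the two head
# probability outputs. Returns gradients for every parameter tensor.
crfe_backward <- function(model, cache, dprob, daux_prob = NULL) {
  params <- model$params
  g <- list()
  # main head
  dlogit <- dprob * cache$prob * (1 - cache$prob)
  bo <- conv1_backward(dlogit, cache$oc$cache)
  g$out <- list(W = bo$dW, b = bo$db)
  sp3 <- split_channels(bo$dx, dim(cache$u3$out)[3])
  du3 <- sp3$da; de1_skip <- sp3$db
  ddr2 <- upsample2_backward(du3, cache$u3$cache)
  ddc2 <- relu_backward(ddr2, cache$dr2$cache)
  b2 <- conv3_backward(ddc2, cache$dc2$cache)
  g$dec2 <- list(W = b2$dW, b = b2$db)
  sp2 <- split_channels(b2$dx, dim(cache$u2$out)[3])
  du2 <- sp2$da; de2_skip <- sp2$db
  ddr1 <- upsample2_backward(du2, cache$u2$cache)
  ddc1 <- relu_backward(ddr1, cache$dr1$cache)
  b1 <- conv3_backward(ddc1, cache$dc1$cache)
  g$dec1 <- list(W = b1$dW, b = b1$db)
  sp1 <- split_channels(b1$dx, dim(cache$u1$out)[3])
  du1 <- sp1$da; de3_skip <- sp1$db
  dat <- upsample2_backward(du1, cache$u1$cache)
  # aux head
  if (!is.null(daux_prob)) {
    dlogit_aux <- daux_prob * cache$aux_prob * (1 - cache$aux_prob)
    ba <- conv1_backward(dlogit_aux, cache$auxc$cache)
    g$aux <- list(W = ba$dW, b = ba$db)
    dat <- dat + ba$dx
  } else {
    g$aux <- list(W = params$aux$W * 0, b = 0)
  }
  # attention
  ab <- attention_backward(dat, cache$at$cache, params$att)
  g$att <- list(Wb = ab$dWb, Wc = ab$dWc, Wd = ab$dWd, alpha = ab$dalpha)
  # recurrent context
  rb <- recurrent_context_backward(ab$dx, cache$rc$cache, params)
  g$lstm_f <- rb$grads$lstm_f
  g$lstm_b <- rb$grads$lstm_b
  g$proj <- rb$grads$proj
  # encoder (through pools and skips)
  enc <- cache$enc
  dp3 <- maxpool_backward(rb$dx, enc$p3$cache)
  # e3 receives both the pooled path and the skip connection
  dr3 <- relu_backward(dp3 + de3_skip, enc$r3$cache)
  b3 <- conv3_backward(dr3, enc$c3$cache)
  g$enc3 <- list(W = b3$dW, b = b3$db)
  dp2 <- maxpool_backward(b3$dx, enc$p2$cache)
  dr2e <- relu_backward(dp2 + de2_skip, enc$r2$cache)
  b2e <- conv3_backward(dr2e, enc$c2$cache)
  g$enc2 <- list(W = b2e$dW, b = b2e$db)
  dp1 <- maxpool_backward(b2e$dx, enc$p1$cache)
  dr1e <- relu_backward(dp1 + de1_skip, enc$r1$cache)
  b1e <- conv3_backward(dr1e, enc$c1$cache)
  g$enc1 <- list(W = b1e$dW, b = b1e$db)
  g
}

#' Predict probability maps for a list of images
#'
#' Images are z-scored slice-wise before the forward pass (matching the
#' training-time standardisation).
#'
#' @param model a trained `crfe_model`.
#' @param images list of matrices (or a single matrix).
#' @param standardize z-score each slice first, default TRUE.
#' @return list of probability matrices.
#' @export
crfe_predict <- function(model, images, standardize = TRUE) {
  if (is.matrix(images)) images <- list(images)
  lapply(images, function(im) {
    if (standardize) im <- zscore(im)
    p <- crfe_forward(model, im)$prob
    matrix(p[, , 1, 1], nrow(im), ncol(im))
  })
}
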
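# Low-level differentiable layers for the CRFE network.
#
# Feature maps are arrays (H, W, C, B). Convolution weights for 3x3 kernels
# are stored as matrices (9*Cin, Cout) with row index = offset + 9*(ch-1);
# the nine offsets enumerate (dr, dc) with dr in -1:1 varying fastest.
# Every *_forward returns a cache consumed by the matching *_backward, which
# returns the input gradient plus parameter gradients. The whole stack is
# validated against central-difference gradients in the test suite.

#' Rectified linear unit
#' @param x numeric scalar, vector or array.
#' @return elementwise `max(0, x)`.
#' @export
relu <- function(x) pmax(x, 0)

#' Logistic sigmoid
#' @param x numeric input.
#' @return `1 / (1 + exp(-x))`, elementwise, in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# im2col linear indices into the zero-padded (H+2)x(W+2) grid, for all
# output positions (column-major) and the 9 kernel offsets.
conv3_indices <- function(H, W) {
  r <- rep(seq_len(H), W)
  cl <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  o <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      o <- o + 1L
      idx[, o] <- (r + dr + 1L) + (cl + dc) * (H + 2L)
    }
  }
  idx
}

conv3_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  idx <- conv3_indices(H, Wd)
  HW <- H * Wd
  P <- matrix(0, B * HW, 9L * Cin)
  for (bi in seq_len(B)) {
    padarr <- array(0, c(H + 2L, Wd + 2L, Cin))
    padarr[2:(H + 1L), 2:(Wd + 1L), ] <- x[, , , bi]
    dim(padarr) <- c((H + 2L) * (Wd + 2L), Cin)
    Pl <- padarr[as.vector(idx), , drop = FALSE]   # (HW*9) x Cin
    dim(Pl) <- c(HW, 9L, Cin)
    dim(Pl) <- c(HW, 9L * Cin)
    P[(bi - 1L) * HW + seq_len(HW), ] <- Pl
  }
  Y <- P %*% W
  Y <- sweep(Y, 2L, b, "+")
  Cout <- ncol(W)
  y <- array(Y, c(H, Wd, B, Cout))
  y <- aperm(y, c(1, 2, 4, 3))
  list(out = y, cache = list(P = P, dims = d, idx = idx, W = W))
}

conv3_backward <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  HW <- H * Wd
  Cout <- dim(dy)[3]
  dY <- matrix(aperm(dy, c(1, 2, 4, 3)), B * HW, Cout)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(cache$W)                          # (B*HW) x 9Cin
  dx <- array(0, d)
  idx <- cache$idx
  for (bi in seq_len(B)) {
    dpad <- matrix(0, (H + 2L) * (Wd + 2L), Cin)
    dPb <- dP[(bi - 1L) * HW + seq_len(HW), , drop = FALSE]
    dim(dPb) <- c(HW, 9L, Cin)
    for (o in 1:9) {
      dpad[idx[, o], ] <- dpad[idx[, o], ] + dPb[, o, ]
    }
    dim(dpad) <- c(H + 2L, Wd + 2L, Cin)
    dx[, , , bi] <- dpad[2:(H + 1L), 2:(Wd + 1L), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

conv1_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), H * Wd * B, Cin)
  Y <- sweep(xm %*% W, 2L, b, "+")
  Cout <- ncol(W)
  y <- aperm(array(Y, c(H, Wd, B, Cout)), c(1, 2, 4, 3))
  list(out = y, cache = list(xm = xm, dims = d, W = W))
}

conv1_backward <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  Cout <- dim(dy)[3]
  dY <- matrix(aperm(dy, c(1, 2, 4, 3)), H * Wd * B, Cout)
  dW <- crossprod(cache$xm, dY)
  db <- colSums(dY)
  dxm <- dY %*% t(cache$W)
  dx <- aperm(array(dxm, c(H, Wd, B, Cin)), c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dy, cache) dy * cache

maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, W, 2L); je <- seq(2L, W, 2L)
  v1 <- x[io, jo, , , drop = FALSE]
  v2 <- x[ie, jo, , , drop = FALSE]
  v3 <- x[io, je, , , drop = FALSE]
  v4 <- x[ie, je, , , drop = FALSE]
  y <- pmax(v1, v2, v3, v4)
  which4 <- array(1L, dim(y))
  which4[v2 == y & v1 < y] <- 2L
  which4[v3 == y & v1 < y & v2 < y] <- 3L
  which4[v4 == y & v1 < y & v2 < y & v3 < y] <- 4L
  list(out = y, cache = list(which4 = which4, dims = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, W, 2L); je <- seq(2L, W, 2L)
  w4 <- cache$which4
  dx <- array(0, d)
  dx[io, jo, , ] <- dy * (w4 == 1L)
  dx[ie, jo, , ] <- dy * (w4 == 2L)
  dx[io, je, , ] <- dy * (w4 == 3L)
  dx[ie, je, , ] <- dy * (w4 == 4L)
  dx
}

# Bilinear 2x upsampling expressed as a fixed linear map per axis:
# out = U_r %*% X %*% t(U_c). Half-pixel output centers, edge-clamped.
upsample2_matrix <- function(H) {
  U <- matrix(0, 2L * H, H)
  for (i in seq_len(2L * H)) {
    s <- (i - 0.5) / 2 + 0.5          # source coordinate, 1-based
    s <- min(max(s, 1), H)
    i0 <- floor(s); f <- s - i0
    if (i0 >= H) { i0 <- H; f <- 0 }
    U[i, i0] <- U[i, i0] + (1 - f)
    if (f > 0) U[i, i0 + 1L] <- U[i, i0 + 1L] + f
  }
  U
}

apply_rowcol <- function(x, Ur, Uc) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  t1 <- Ur %*% matrix(x, H, W * C * B)
  Ho <- nrow(Ur)
  t1 <- array(t1, c(Ho, W, C, B))
  t1 <- aperm(t1, c(2, 1, 3, 4))
  t2 <- Uc %*% matrix(t1, W, Ho * C * B)
  Wo <- nrow(Uc)
  t2 <- array(t2, c(Wo, Ho, C, B))
  aperm(t2, c(2, 1, 3, 4))
}

upsample2_forward <- function(x) {
  d <- dim(x)
  Ur <- upsample2_matrix(d[1]); Uc <- upsample2_matrix(d[2])
  list(out = apply_rowcol(x, Ur, Uc), cache = list(Ur = Ur, Uc = Uc))
}

upsample2_backward <- function(dy, cache) {
  apply_rowcol(dy, t(cache$Ur), t(cache$Uc))
}

concat_channels <- function(a, b) {
  d1 <- dim(a); d2 <- dim(b)
  stopifnot(all(d1[c(1, 2, 4)] == d2[c(1, 2, 4)]))
  out <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
  out[, , seq_len(d1[3]), ] <- a
  out[, , d1[3] + seq_len(d2[3]), ] <- b
  out
}

split_channels <- function(dx, c1) {
  d <- dim(dx)
  list(da = dx[, , seq_len(c1), , drop = FALSE],
       db = dx[, , (c1 + 1L):d[3], , drop = FALSE])
}

# ---- LSTM ----------------------------------------------------------------

lstm_forward <- function(X, params) {
  # X: list of N matrices (B x Cin)
  N <- length(X); B <- nrow(X[[1]]); U <- nrow(params$Wh)
  h <- matrix(0, B, U); cs <- matrix(0, B, U)
  Hs <- vector("list", N); cache <- vector("list", N)
  for (t in seq_len(N)) {
    G <- X[[t]] %*% params$Wx + h %*% params$Wh +
      matrix(params$b, B, 4L * U, byrow = TRUE)
    i <- sigmoid(G[, seq_len(U), drop = FALSE])
    f <- sigmoid(G[, U + seq_len(U), drop = FALSE])
    o <- sigmoid(G[, 2L * U + seq_len(U), drop = FALSE])
    g <- tanh(G[, 3L * U + seq_len(U), drop = FALSE])
    cprev <- cs
    cs <- f * cprev + i * g
    hct <- tanh(cs)
    hprev <- h
    h <- o * hct
    Hs[[t]] <- h
    cache[[t]] <- list(X = X[[t]], i = i, f = f, o = o, g = g,
                       cprev = cprev, cs = cs, hct = hct, hprev = hprev)
  }
  list(H = Hs, cache = cache)
}

lstm_backward <- function(dH, cache, params) {
  N <- length(dH); B <- nrow(dH[[1]]); U <- nrow(params$Wh)
  Cin <- nrow(params$Wx)
  dWx <- matrix(0, Cin, 4L * U); dWh <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dh_carry <- matrix(0, B, U); dc_carry <- matrix(0, B, U)
  dX <- vector("list", N)
  for (t in rev(seq_len(N))) {
    cc <- cache[[t]]
    dh <- dH[[t]] + dh_carry
    do_ <- dh * cc$hct
    dhc <- dh * cc$o
    dc <- dc_carry + dhc * (1 - cc$hct^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$cprev
    dc_carry <- dc * cc$f
    dGi <- di * cc$i * (1 - cc$i)
    dGf <- df * cc$f * (1 - cc$f)
    dGo <- do_ * cc$o * (1 - cc$o)
    dGg <- dg * (1 - cc$g^2)
    dG <- cbind(dGi, dGf, dGo, dGg)
    dWx <- dWx + crossprod(cc$X, dG)
    dWh <- dWh + crossprod(cc$hprev, dG)
    db <- db + colSums(dG)
    dh_carry <- dG %*% t(params$Wh)
    dX[[t]] <- dG %*% t(params$Wx)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# Serialize a feature block (H,W,C,B) into a row-major sequence of
# (B x C) matrices: position t = (r-1)*W + c.
serialize_rowmajor <- function(fm) {
  d <- dim(fm); H <- d[1]; W <- d[2]
  ap <- aperm(fm, c(4, 3, 2, 1))       # (B, C, W, H)
  X <- vector("list", H * W)
  t0 <- 0L
  for (r in seq_len(H)) {
    for (cl in seq_len(W)) {
      t0 <- t0 + 1L
      X[[t0]] <- ap[, , cl, r, drop = TRUE]
      if (is.null(dim(X[[t0]]))) {
        X[[t0]] <- matrix(X[[t0]], d[4], d[3])
      }
    }
  }
  X
}

deserialize_rowmajor <- function(X, H, W) {
  B <- nrow(X[[1]]); C <- ncol(X[[1]])
  fm <- array(0, c(H, W, C, B))
  t0 <- 0L
  for (r in seq_len(H)) {
    for (cl in seq_len(W)) {
      t0 <- t0 + 1L
      fm[r, cl, , ] <- t(X[[t0]])
    }
  }
  fm
}
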
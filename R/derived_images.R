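#' The nine-filter derived-image bank
#'
#' Radiomics features are computed on the original slice and on eight
#' filtered versions of it:
#' \itemize{
#'   \item `original` -- identity;
#'   \item `log_sigma_1_0_mm`, `log_sigma_2_0_mm` -- Laplacian-of-Gaussian
#'     band-pass responses, sigma given in mm and converted to pixels via
#'     the pixel spacing;
#'   \item `wavelet_L`, `wavelet_H` -- single-level Daubechies-2 wavelet
#'     approximation and aggregated detail, each reconstructed to the
#'     original size (they sum to the original image);
#'   \item `exponential`, `logarithm`, `square`, `square_root` --
#'     monotone intensity transforms (logarithm and square root shift to
#'     positive support first).
#' }
#'
#' @param image 2-D numeric matrix (even side lengths for the wavelet
#'   filters).
#' @param spacing mm per pixel (> 0).
#' @return named list of 9 matrices in canonical order.
#' @export
derive_images <- function(image, spacing = 1) {
  stopifnot(is.matrix(image), all(is.finite(image)), spacing > 0)
  wl <- dwt2_single(image)
  mn <- min(image)
  mx_abs <- max(abs(image))
  list(
    original = image,
    log_sigma_1_0_mm = log_filter(image, 1.0 / spacing),
    log_sigma_2_0_mm = log_filter(image, 2.0 / spacing),
    wavelet_L = wl$approx,
    wavelet_H = wl$detail,
    exponential = if (mx_abs == 0) image + 1 else exp(image / mx_abs),
    logarithm = log1p(image - mn),
    square = image^2,
    square_root = sqrt(image - min(mn, 0))
  )
}

#' Canonical derived-image kind names
#' @return character vector of length 9.
#' @export
derived_image_kinds <- function() {
  c("original", "log_sigma_1_0_mm", "log_sigma_2_0_mm",
    "wavelet_L", "wavelet_H",
    "exponential", "logarithm", "square", "square_root")
}

# Laplacian of Gaussian: separable Gaussian smoothing (edge-clamped)
# followed by the 5-point discrete Laplacian, scale-normalised by sigma^2.
# Constant images map to exactly zero.
log_filter <- function(image, sigma_px) {
  sm <- gaussian_smooth(image, sigma_px)
  n <- nrow(sm); m <- ncol(sm)
  up <- sm[c(1, seq_len(n - 1)), ]
  dn <- sm[c(seq_len(n - 1) + 1, n), ]
  lf <- sm[, c(1, seq_len(m - 1))]
  rt <- sm[, c(seq_len(m - 1) + 1, m)]
  sigma_px^2 * (up + dn + lf + rt - 4 * sm)
}

# Daubechies-2 (4-tap) orthonormal filter pair.
db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))   # low-pass
  g <- rev(h) * c(1, -1, 1, -1)                            # high-pass (QMF)
  list(h = h, g = g)
}

# Periodic 1-D analysis: returns approx and detail coefficients (length n/2).
dwt1 <- function(x, h, g) {
  n <- length(x)
  idx <- function(i) ((i - 1) %% n) + 1
  starts <- seq(1, n, 2)
  a <- numeric(n / 2); d <- numeric(n / 2)
  for (k in seq_along(starts)) {
    ii <- idx(starts[k] + 0:3)
    a[k] <- sum(h * x[ii])
    d[k] <- sum(g * x[ii])
  }
  list(a = a, d = d)
}

# Periodic 1-D synthesis (adjoint of the analysis operator).
idwt1 <- function(a, d, h, g) {
  n <- 2 * length(a)
  x <- numeric(n)
  idx <- function(i) ((i - 1) %% n) + 1
  starts <- seq(1, n, 2)
  for (k in seq_along(starts)) {
    ii <- idx(starts[k] + 0:3)
    x[ii] <- x[ii] + a[k] * h + d[k] * g
  }
  x
}

# Single-level separable 2-D DWT; returns the approximation image (LL
# reconstructed alone) and the aggregated detail image (LH+HL+HH
# reconstructed), both at the original size. Orthonormality implies
# approx + detail == original.
dwt2_single <- function(image) {
  n <- nrow(image); m <- ncol(image)
  if (n %% 2L != 0L || m %% 2L != 0L) {
    stop("wavelet filtering needs even image sides")
  }
  fl <- db2_filters()
  # analyse columns
  ca <- matrix(0, n / 2, m); cd <- matrix(0, n / 2, m)
  for (j in seq_len(m)) {
    w <- dwt1(image[, j], fl$h, fl$g)
    ca[, j] <- w$a; cd[, j] <- w$d
  }
  # analyse rows of both
  LL <- matrix(0, n / 2, m / 2); LH <- matrix(0, n / 2, m / 2)
  HL <- matrix(0, n / 2, m / 2); HH <- matrix(0, n / 2, m / 2)
  for (i in seq_len(n / 2)) {
    w <- dwt1(ca[i, ], fl$h, fl$g)
    LL[i, ] <- w$a; LH[i, ] <- w$d
    w <- dwt1(cd[i, ], fl$h, fl$g)
    HL[i, ] <- w$a; HH[i, ] <- w$d
  }
  recon <- function(ll, lh, hl, hh) {
    ca2 <- matrix(0, n / 2, m); cd2 <- matrix(0, n / 2, m)
    for (i in seq_len(n / 2)) {
      ca2[i, ] <- idwt1(ll[i, ], lh[i, ], fl$h, fl$g)
      cd2[i, ] <- idwt1(hl[i, ], hh[i, ], fl$h, fl$g)
    }
    out <- matrix(0, n, m)
    for (j in seq_len(m)) {
      out[, j] <- idwt1(ca2[, j], cd2[, j], fl$h, fl$g)
    }
    out
  }
  z <- matrix(0, n / 2, m / 2)
  approx <- recon(LL, z, z, z)
  detail <- recon(z, LH, HL, HH)
  list(approx = approx, detail = detail,
       LL = LL, LH = LH, HL = HL, HH = HH)
}
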
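#' Augmentation configuration
#'
#' Stochastic augmentation mirrors common MRI training practice: random
#' rotation within +/- 15 degrees, random horizontal/vertical flips, random
#' scaling in 0.9--1.1, and additive Gaussian noise with standard deviation
#' 0.01 (applied to the image only).
#'
#' @param rotation_limit degrees, default 15.
#' @param flip_horizontal,flip_vertical enable flags, default TRUE.
#' @param scale_range multiplicative interval, default `c(0.9, 1.1)`.
#' @param gaussian_noise_sd intensity units, default 0.01.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_limit = 15,
                                flip_horizontal = TRUE,
                                flip_vertical = TRUE,
                                scale_range = c(0.9, 1.1),
                                gaussian_noise_sd = 0.01) {
  stopifnot(rotation_limit >= 0,
            length(scale_range) == 2L, all(scale_range > 0),
            scale_range[1] <= scale_range[2],
            gaussian_noise_sd >= 0)
  structure(list(rotation_limit = rotation_limit,
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 scale_range = as.numeric(scale_range),
                 gaussian_noise_sd = gaussian_noise_sd),
            class = "augmentation_config")
}

# Inverse-map affine sampler. For each output pixel, the inverse transform
# (rotation by -theta, scaling by 1/s, optional flips, all about the image
# center) locates a source coordinate; images are sampled bilinearly with
# reflection padding, masks nearest-neighbour with zero padding (so no lesion
# pixels are fabricated at borders).
affine_sample <- function(x, theta_deg = 0, scale = 1,
                          flip_h = FALSE, flip_v = FALSE,
                          interp = c("bilinear", "nearest"),
                          pad = c("reflect", "zero"),
                          out_dim = dim(x)) {
  interp <- match.arg(interp)
  pad <- match.arg(pad)
  n <- nrow(x); m <- ncol(x)
  no <- out_dim[1]; mo <- out_dim[2]
  th <- theta_deg * pi / 180
  # output pixel centers relative to output center
  rc <- (seq_len(no) - (no + 1) / 2)
  cc <- (seq_len(mo) - (mo + 1) / 2)
  R <- matrix(rc, no, mo)
  C <- matrix(cc, no, mo, byrow = TRUE)
  if (flip_h) C <- -C
  if (flip_v) R <- -R
  # inverse rotation & scale
  Rs <- (cos(th) * R + sin(th) * C) / scale
  Cs <- (-sin(th) * R + cos(th) * C) / scale
  # to source pixel coordinates
  Rs <- Rs + (n + 1) / 2
  Cs <- Cs + (m + 1) / 2
  reflect_idx <- function(i, len) {
    # reflect about pixel centers: period 2*(len-1)
    if (len == 1L) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * (len - 1L))
    j <- ifelse(j < 0L, j + 2L * (len - 1L), j)
    as.integer(ifelse(j >= len, 2L * (len - 1L) - j, j) + 1L)
  }
  if (interp == "nearest") {
    ri <- round(Rs); ci <- round(Cs)
    inside <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    out <- matrix(0, no, mo)
    if (pad == "reflect") {
      out[] <- x[cbind(reflect_idx(as.integer(ri), n),
                       reflect_idx(as.integer(ci), m))]
    } else {
      out[inside] <- x[cbind(as.integer(ri[inside]), as.integer(ci[inside]))]
    }
    return(out)
  }
  r0 <- floor(Rs); c0 <- floor(Cs)
  fr <- Rs - r0; fc <- Cs - c0
  grab <- function(ri, ci) {
    if (pad == "reflect") {
      x[cbind(reflect_idx(as.integer(ri), n), reflect_idx(as.integer(ci), m))]
    } else {
      v <- numeric(length(ri))
      ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
      v[ok] <- x[cbind(as.integer(ri[ok]), as.integer(ci[ok]))]
      v
    }
  }
  v00 <- grab(r0, c0); v01 <- grab(r0, c0 + 1)
  v10 <- grab(r0 + 1, c0); v11 <- grab(r0 + 1, c0 + 1)
  out <- (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
  matrix(out, no, mo)
}

#' Resample a 2-D grid to a new pixel spacing
#'
#' Output extent is `round(extent * source_spacing / target_spacing)`;
#' interpolation is bilinear for images and nearest-neighbour for masks
#' (`method = "nearest"`). Source equal to target returns the input
#' unchanged.
#'
#' @param image 2-D numeric matrix.
#' @param source_spacing,target_spacing mm per pixel, > 0.
#' @param method "linear" (default) or "nearest".
#' @return resampled matrix.
#' @export
resample <- function(image, source_spacing, target_spacing,
                     method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (source_spacing <= 0 || target_spacing <= 0) {
    stop("spacings must be positive")
  }
  if (source_spacing == target_spacing) return(image)
  f <- source_spacing / target_spacing
  out_dim <- c(max(1L, as.integer(round(nrow(image) * f))),
               max(1L, as.integer(round(ncol(image) * f))))
  affine_sample(image, theta_deg = 0, scale = f,
                interp = if (method == "linear") "bilinear" else "nearest",
                pad = "reflect", out_dim = out_dim)
}

#' Z-score standardization of an image
#'
#' @param image 2-D numeric matrix with at least two distinct values.
#' @return matrix with mean 0 and SD 1.
#' @export
zscore <- function(image) {
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant image")
  (image - mean(image)) / s
}

#' Apply one random augmentation draw to a phantom
#'
#' A single geometric transform (rotation, flips, scaling) is applied
#' identically to image and mask; Gaussian noise is added to the image only;
#' the mask stays binary. The draw consumes the current RNG stream, so seed
#' externally for reproducibility.
#'
#' @param phantom a `phantom` (or any list with `image` and `mask`).
#' @param config an [augmentation_config()].
#' @return phantom with augmented `image` and `mask`.
#' @export
augment <- function(phantom, config) {
  stopifnot(inherits(config, "augmentation_config"))
  theta <- if (config$rotation_limit > 0) {
    stats::runif(1, -config$rotation_limit, config$rotation_limit)
  } else 0
  s <- if (diff(config$scale_range) > 0) {
    stats::runif(1, config$scale_range[1], config$scale_range[2])
  } else config$scale_range[1]
  fh <- config$flip_horizontal && stats::runif(1) < 0.5
  fv <- config$flip_vertical && stats::runif(1) < 0.5
  identity_geom <- theta == 0 && s == 1 && !fh && !fv
  img <- phantom$image
  msk <- phantom$mask
  if (!identity_geom) {
    img <- affine_sample(img, theta, s, fh, fv,
                         interp = "bilinear", pad = "reflect")
    msk <- affine_sample(msk, theta, s, fh, fv,
                         interp = "nearest", pad = "zero")
  }
  if (config$gaussian_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, config$gaussian_noise_sd),
                        nrow(img), ncol(img))
  }
  phantom$image <- img
  phantom$mask <- matrix(as.integer(msk != 0), nrow(msk), ncol(msk))
  phantom
}

#' Train/validation/test split specification
#'
#' @param fractions numeric triple (train, validation, test) summing to 1;
#'   default 0.70/0.15/0.15.
#' @param seed shuffling seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(fractions = as.numeric(fractions), seed = as.integer(seed)),
            class = "split_spec")
}

#' Split subject ids into train/validation/test
#'
#' Validation and test sizes are `floor(fraction * n)`; the remainder goes
#' to training, so 141 subjects under 0.70/0.15/0.15 split as (99, 21, 21).
#' Shuffling is seeded; the partition is disjoint and exhaustive.
#'
#' @param ids vector of unique subject ids.
#' @param spec a [split_spec()].
#' @return list with `train`, `validation`, `test`.
#' @export
split_cohort <- function(ids, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (length(ids) == 0L) stop("ids must be non-empty")
  if (anyDuplicated(ids)) stop("duplicate ids are not allowed")
  n <- length(ids)
  n_val <- floor(spec$fractions[2] * n)
  n_test <- floor(spec$fractions[3] * n)
  if (spec$fractions[1] == 1) { n_val <- 0L; n_test <- 0L }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  perm <- sample(ids)
  val <- if (n_val > 0) perm[seq_len(n_val)] else ids[0]
  test <- if (n_test > 0) perm[n_val + seq_len(n_test)] else ids[0]
  train <- perm[setdiff(seq_len(n), seq_len(n_val + n_test))]
  list(train = train, validation = val, test = test)
}
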
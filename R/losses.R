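#' Loss configuration for the composite segmentation objective
#'
#' The total objective sums per-module Dice + cross-entropy terms, a
#' lambda-weighted set of global consistency terms, and a clinical size
#' prior penalising predicted lesions whose equivalent diameter falls
#' outside 10--40 mm.
#'
#' @param epsilon Dice smoothing constant, default 1e-6.
#' @param lambda_global weight of the global constraint terms, default 1.
#' @param size_prior_mm diameter interval in mm, default `c(10, 40)`.
#' @param pixel_spacing mm per pixel used to convert predicted area to an
#'   equivalent diameter.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(epsilon = 1e-6, lambda_global = 1,
                        size_prior_mm = c(10, 40), pixel_spacing = 0.5) {
  stopifnot(epsilon > 0, lambda_global >= 0,
            length(size_prior_mm) == 2L, size_prior_mm[1] > 0,
            size_prior_mm[2] > size_prior_mm[1], pixel_spacing > 0)
  structure(list(epsilon = epsilon, lambda_global = lambda_global,
                 size_prior_mm = as.numeric(size_prior_mm),
                 pixel_spacing = pixel_spacing),
            class = "loss_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`.
#'
#' @param pred probability map in [0,1].
#' @param target binary mask of the same shape.
#' @param epsilon smoothing constant.
#' @return scalar in [0, 1).
#' @export
dice_loss <- function(pred, target, epsilon = 1e-6) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  inter <- sum(pred * target)
  1 - (2 * inter + epsilon) / (sum(pred) + sum(target) + epsilon)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))`, with predictions
#' clipped away from 0 and 1 for stability.
#'
#' @param pred probability map.
#' @param target binary mask.
#' @param clip clipping bound, default 1e-7.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(pred, target, clip = 1e-7) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  p <- pmin(pmax(pred, clip), 1 - clip)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Clinical size-prior loss
#'
#' The predicted equivalent diameter is
#' `d = 2 * sqrt(sum(pred) * spacing^2 / pi)` (soft pixel count). The loss
#' is 0 when d lies inside the prior interval (bounds inclusive) and the
#' squared distance to the nearest bound, normalised by the squared interval
#' width, otherwise.
#'
#' @param pred probability map.
#' @param config a [loss_config()].
#' @return non-negative scalar.
#' @export
size_prior_loss <- function(pred, config) {
  stopifnot(inherits(config, "loss_config"))
  d <- 2 * sqrt(sum(pred) * config$pixel_spacing^2 / pi)
  lo <- config$size_prior_mm[1]; hi <- config$size_prior_mm[2]
  w <- hi - lo
  if (d < lo) ((lo - d) / w)^2 else if (d > hi) ((d - hi) / w)^2 else 0
}

#' Composite training loss
#'
#' `sum(module_losses) + lambda * sum(global_losses) + size_loss`.
#'
#' @param module_losses numeric vector of per-module (deep supervision)
#'   losses.
#' @param global_losses numeric vector of global consistency losses.
#' @param size_loss scalar size-prior loss.
#' @param config a [loss_config()] providing `lambda_global`.
#' @return scalar.
#' @export
total_loss <- function(module_losses, global_losses, size_loss, config) {
  stopifnot(inherits(config, "loss_config"))
  sum(module_losses) + config$lambda_global * sum(global_losses) + size_loss
}

#' Cosine-annealing schedule configuration
#'
#' @param eta_min minimum learning rate, default 1e-5.
#' @param eta_max maximum learning rate, default 0.001 (the Adam initial
#'   learning rate).
#' @param T_i iterations per cosine cycle (>= 1).
#' @return object of class `schedule_config`.
#' @export
schedule_config <- function(eta_min = 1e-5, eta_max = 0.001, T_i = 100L) {
  stopifnot(eta_min >= 0, eta_min <= eta_max, T_i >= 1)
  structure(list(eta_min = eta_min, eta_max = eta_max, T_i = as.numeric(T_i)),
            class = "schedule_config")
}

#' Cosine-annealed learning rate
#'
#' `eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(pi * T_cur / T_i))`,
#' monotone non-increasing over one cycle; `T_cur` must lie in `[0, T_i]`
#' (cycle restarts are the caller's business).
#'
#' @param T_cur current iteration within the cycle.
#' @param config a [schedule_config()].
#' @return learning rate.
#' @export
cosine_lr <- function(T_cur, config) {
  stopifnot(inherits(config, "schedule_config"))
  if (any(T_cur < 0) || any(T_cur > config$T_i)) {
    stop("T_cur must lie in [0, T_i]")
  }
  config$eta_min + 0.5 * (config$eta_max - config$eta_min) *
    (1 + cos(pi * T_cur / config$T_i))
}

# ---- analytic gradients used by the trainer ------------------------------

# d dice_loss / d pred (elementwise)
dice_loss_grad <- function(pred, target, epsilon = 1e-6) {
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target) + epsilon
  num <- 2 * inter + epsilon
  -(2 * target * denom - num) / denom^2
}

# d cross_entropy_loss / d pred (elementwise, mean reduction)
cross_entropy_loss_grad <- function(pred, target, clip = 1e-7) {
  p <- pmin(pmax(pred, clip), 1 - clip)
  g <- (-target / p + (1 - target) / (1 - p)) / length(pred)
  g[pred < clip & target == 0] <- 0   # clipped region: flat
  g[pred > 1 - clip & target == 1] <- 0
  g
}

# d size_prior_loss / d pred (elementwise; depends on pred only via its sum)
size_prior_loss_grad <- function(pred, config) {
  sp <- config$pixel_spacing
  s <- sum(pred)
  d <- 2 * sqrt(s * sp^2 / pi)
  lo <- config$size_prior_mm[1]; hi <- config$size_prior_mm[2]
  w <- hi - lo
  if (d >= lo && d <= hi) return(array(0, dim(pred)))
  dd_ds <- sp / sqrt(pi * max(s, 1e-6))
  dl_dd <- if (d < lo) -2 * (lo - d) / w^2 else 2 * (d - hi) / w^2
  array(dl_dd * dd_ds, dim(pred))
}
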
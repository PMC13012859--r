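#' Pixel-wise overlap metrics between two binary masks
#'
#' Counts TP/FP/FN/TN per pixel and reports foreground IoU, class-averaged
#' IoU (mean of foreground and background IoU), Dice, F1 (harmonic mean of
#' precision and recall -- identical to Dice for binary masks), accuracy,
#' precision, recall and specificity. Both IoU variants are reported because
#' "IoU" in the segmentation literature sometimes averages over classes
#' including background; callers must pick explicitly.
#'
#' @param pred_mask,true_mask binary matrices of identical shape.
#' @return list of class `seg_metrics` with the metric fields plus the raw
#'   confusion counts.
#' @export
overlap_metrics <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask))) stop("shape mismatch")
  if (!all(pred_mask %in% c(0, 1)) || !all(true_mask %in% c(0, 1))) {
    stop("masks must be binary")
  }
  p <- pred_mask != 0; t <- true_mask != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  safe <- function(num, den) if (den == 0) 1 else num / den
  iou_fg <- safe(tp, tp + fp + fn)
  iou_bg <- safe(tn, tn + fp + fn)
  dice <- safe(2 * tp, 2 * tp + fp + fn)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  specificity <- safe(tn, tn + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 iou_foreground = iou_fg,
                 iou_all_pixels = (iou_fg + iou_bg) / 2,
                 dice = dice, f1 = f1,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 precision = precision, recall = recall,
                 specificity = specificity),
            class = "seg_metrics")
}

#' Mean absolute error between a probability map and a mask
#'
#' `mean(|pred - true|)`, multiplied by a reporting scale (default 100,
#' matching the percentage-like magnitude convention common in segmentation
#' reports). The raw (scale 1) value is what the formula defines.
#'
#' @param pred probability map.
#' @param true_mask binary mask.
#' @param scale reporting multiplier, default 100.
#' @return scalar.
#' @export
mae_metric <- function(pred, true_mask, scale = 100) {
  if (!all(dim(pred) == dim(true_mask))) stop("shape mismatch")
  scale * mean(abs(pred - true_mask))
}

# Boundary pixels of a binary mask: foreground pixels with at least one
# 4-neighbour outside the mask (image border counts as outside).
boundary_pixels <- function(mask) {
  m <- mask != 0
  n <- nrow(m); k <- ncol(m)
  padded <- matrix(FALSE, n + 2, k + 2)
  padded[2:(n + 1), 2:(k + 1)] <- m
  inner <- padded[2:(n + 1), 2:(k + 1)] &
    !(padded[1:n, 2:(k + 1)] & padded[3:(n + 2), 2:(k + 1)] &
        padded[2:(n + 1), 1:k] & padded[2:(n + 1), 3:(k + 2)])
  which(inner, arr.ind = TRUE)
}

#' Symmetric Hausdorff distance between two masks
#'
#' Maximum over both directed nearest-boundary distances between the
#' Euclidean boundary pixel sets; reported in pixels and in mm.
#'
#' @param pred_mask,true_mask non-empty binary matrices.
#' @param spacing mm per pixel.
#' @return list with `hausdorff_px` and `hausdorff_mm`.
#' @export
hausdorff <- function(pred_mask, true_mask, spacing = 1) {
  if (sum(pred_mask != 0) == 0 || sum(true_mask != 0) == 0) {
    stop("Hausdorff distance is undefined for an empty mask")
  }
  a <- boundary_pixels(pred_mask)
  b <- boundary_pixels(true_mask)
  # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  dir_ab <- max(apply(d2, 1, min))
  dir_ba <- max(apply(d2, 2, min))
  hd <- sqrt(max(dir_ab, dir_ba))
  list(hausdorff_px = hd, hausdorff_mm = hd * spacing)
}

#' Full segmentation report for one case
#'
#' @param pred probability map.
#' @param true_mask binary mask.
#' @param spacing mm per pixel.
#' @param threshold binarisation threshold for the probability map,
#'   default 0.5.
#' @param mae_scale reporting scale for MAE, default 100.
#' @return `seg_metrics` list extended with `mae`, `hausdorff_px`,
#'   `hausdorff_mm`.
#' @export
segmentation_report <- function(pred, true_mask, spacing = 1,
                                threshold = 0.5, mae_scale = 100) {
  pm <- matrix(as.integer(pred >= threshold), nrow(pred), ncol(pred))
  rep <- overlap_metrics(pm, true_mask)
  rep$mae <- mae_metric(pred, true_mask, scale = mae_scale)
  if (sum(pm) > 0 && sum(true_mask != 0) > 0) {
    hd <- hausdorff(pm, true_mask, spacing)
    rep$hausdorff_px <- hd$hausdorff_px
    rep$hausdorff_mm <- hd$hausdorff_mm
  } else {
    rep$hausdorff_px <- NA_real_
    rep$hausdorff_mm <- NA_real_
  }
  rep
}
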
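# Histogram, shape and first-order features, the 868-entry catalogue, and
# whole-phantom extraction.

#' Histogram features of the masked intensities (9 features)
#'
#' Nine gray-level distribution descriptors with the median first (the
#' headline histogram biomarker): median, mean, mode (center of the fullest
#' of 32 equal-width bins), variance, skewness, kurtosis, energy and
#' entropy of the 32-bin histogram, and interquartile range. Degenerate
#' (constant) regions have variance 0, entropy 0, skewness/kurtosis 0.
#'
#' @param intensities numeric vector of masked pixel values (>= 1 value).
#' @return named numeric vector of length 9.
#' @export
histogram_features <- function(intensities) {
  if (length(intensities) == 0L) stop("empty mask")
  x <- as.numeric(intensities)
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  sdev <- sqrt(v)
  sk <- if (sdev > 0) sum((x - mu)^3) / n / sdev^3 else 0
  ku <- if (sdev > 0) sum((x - mu)^4) / n / sdev^4 else 0
  nb <- 32L
  if (max(x) > min(x)) {
    w <- (max(x) - min(x)) / nb
    bin <- pmin(floor((x - min(x)) / w) + 1L, nb)
    counts <- tabulate(bin, nbins = nb)
    mode_val <- min(x) + (which.max(counts) - 0.5) * w
  } else {
    counts <- c(n, rep(0L, nb - 1L))
    mode_val <- x[1]
  }
  p <- counts / n
  c(hist_Median = stats::median(x),
    hist_Mean = mu,
    hist_Mode = mode_val,
    hist_Variance = v,
    hist_Skewness = sk,
    hist_Kurtosis = ku,
    hist_Energy = sum(p^2),
    hist_Entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
    hist_InterquartileRange = unname(diff(stats::quantile(x, c(0.25, 0.75)))))
}

#' Morphological features of a lesion mask (14 features)
#'
#' 2-D analogues of the standard volumetric shape family, keeping the
#' conventional names: area stands in for volume, perimeter for surface
#' area. The perimeter uses the crack-edge count corrected by pi/4 (the
#' expected digitisation inflation for isotropically oriented boundaries),
#' which makes the sphericity of a rasterised disk approach 1. Axis lengths
#' come from the second central moments of the pixel coordinates
#' (`4 * sqrt(eigenvalue)`), elongation is minor/major; the least-axis and
#' flatness entries duplicate the minor-axis ones in 2-D.
#'
#' @param mask binary matrix with a non-empty lesion.
#' @param spacing mm per pixel.
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = 1) {
  m <- mask != 0
  npx <- sum(m)
  if (npx == 0L) stop("empty mask")
  area <- npx * spacing^2
  # crack-edge perimeter with isotropic correction
  n <- nrow(m); k <- ncol(m)
  padded <- matrix(FALSE, n + 2, k + 2)
  padded[2:(n + 1), 2:(k + 1)] <- m
  cracks <- sum(padded[2:(n + 1), 2:(k + 1)] & !padded[1:n, 2:(k + 1)]) +
    sum(padded[2:(n + 1), 2:(k + 1)] & !padded[3:(n + 2), 2:(k + 1)]) +
    sum(padded[2:(n + 1), 2:(k + 1)] & !padded[2:(n + 1), 1:k]) +
    sum(padded[2:(n + 1), 2:(k + 1)] & !padded[2:(n + 1), 3:(k + 2)])
  perim <- cracks * spacing * pi / 4
  # interior pixels (all 4 neighbours inside)
  interior <- sum(padded[2:(n + 1), 2:(k + 1)] & padded[1:n, 2:(k + 1)] &
                    padded[3:(n + 2), 2:(k + 1)] & padded[2:(n + 1), 1:k] &
                    padded[2:(n + 1), 3:(k + 2)])
  mesh_area <- (interior + (npx - interior) / 2) * spacing^2
  coords <- which(m, arr.ind = TRUE) * spacing
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  covm <- crossprod(cc) / npx
  ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  bp <- boundary_pixels(m) * spacing
  maxdiam <- if (nrow(bp) > 1) {
    aa <- rowSums(bp^2)
    sqrt(max(outer(aa, aa, "+") - 2 * bp %*% t(bp)))
  } else 0
  rows_ext <- (diff(range(which(rowSums(m) > 0))) + 1) * spacing
  cols_ext <- (diff(range(which(colSums(m) > 0))) + 1) * spacing
  sph <- if (perim > 0) 2 * sqrt(pi * area) / perim else 0
  c(shape_MeshVolume = mesh_area,
    shape_VoxelVolume = area,
    shape_SurfaceArea = perim,
    shape_SurfaceVolumeRatio = if (area > 0) perim / area else 0,
    shape_Sphericity = sph,
    shape_Maximum3DDiameter = maxdiam,
    shape_Maximum2DDiameterSlice = maxdiam,
    shape_Maximum2DDiameterColumn = cols_ext,
    shape_Maximum2DDiameterRow = rows_ext,
    shape_MajorAxisLength = major,
    shape_MinorAxisLength = minor,
    shape_LeastAxisLength = minor,
    shape_Elongation = if (major > 0) minor / major else 0,
    shape_Flatness = if (major > 0) minor / major else 0)
}

#' First-order statistics of a masked derived image (18 features)
#'
#' @param values numeric vector of masked pixel values of one derived
#'   image.
#' @param spacing mm per pixel (for the total-energy weighting).
#' @param n_bins histogram bins for entropy/uniformity, default 32.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(values, spacing = 1, n_bins = 32L) {
  if (length(values) == 0L) stop("empty mask")
  x <- as.numeric(values)
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  sdev <- sqrt(v)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  inner <- x[x >= qs[1] & x <= qs[4]]
  if (max(x) > min(x)) {
    w <- (max(x) - min(x)) / n_bins
    bin <- pmin(floor((x - min(x)) / w) + 1L, n_bins)
    p <- tabulate(bin, nbins = n_bins) / n
  } else {
    p <- c(1, rep(0, n_bins - 1L))
  }
  c(fo_Energy = sum(x^2),
    fo_TotalEnergy = spacing^2 * sum(x^2),
    fo_Entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
    fo_Minimum = min(x),
    fo_Percentile10 = qs[1],
    fo_Percentile90 = qs[4],
    fo_Maximum = max(x),
    fo_Mean = mu,
    fo_Median = stats::median(x),
    fo_InterquartileRange = qs[3] - qs[2],
    fo_Range = max(x) - min(x),
    fo_MeanAbsoluteDeviation = mean(abs(x - mu)),
    fo_RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    fo_RootMeanSquared = sqrt(mean(x^2)),
    fo_Skewness = if (sdev > 0) sum((x - mu)^3) / n / sdev^3 else 0,
    fo_Kurtosis = if (sdev > 0) sum((x - mu)^4) / n / sdev^4 else 0,
    fo_Variance = v,
    fo_Uniformity = sum(p^2))
}

#' The ordered 868-entry feature catalogue
#'
#' 8 clinical + 14 shape + 9 histogram + 9 derived images x (18 first-order
#' + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM) = 868 named
#' entries.
#'
#' @return data.frame with columns `name`, `family`, `image` (derived-image
#'   kind, NA for clinical/shape/histogram).
#' @export
feature_catalogue <- function() {
  clin <- c("age", "hpv_status", "figo_stage", "lymph_node_metastasis",
            "lymphovascular_invasion", "invasion_depth", "chemotherapy",
            "radiotherapy")
  rows <- list(data.frame(name = paste0("clinical_", clin),
                          family = "clinical", image = NA_character_))
  sh <- names(shape_features(matrix(c(0, 1, 1, 0), 2, 2)))
  rows <- c(rows, list(data.frame(name = sh, family = "shape",
                                  image = NA_character_)))
  hi <- names(histogram_features(c(1, 2)))
  rows <- c(rows, list(data.frame(name = hi, family = "histogram",
                                  image = NA_character_)))
  tmset <- texture_matrices(matrix(c(1, 2, 3, 4), 2, 2), matrix(1, 2, 2), 2L)
  fo <- names(first_order_features(c(1, 2)))
  tx <- texture_features(tmset)
  fam_of <- function(nm) sub("_.*", "", nm)
  for (img in derived_image_kinds()) {
    nm <- c(fo, names(tx))
    rows <- c(rows, list(data.frame(name = paste0(nm, "__", img),
                                    family = fam_of(nm), image = img)))
  }
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  cat
}

#' Extract the full radiomics + clinical feature vector for one phantom
#'
#' Clinical covariates are encoded numerically (hpv: positive 1 / negative
#' 0 / unknown 0.5; FIGO: ordinal 1/2/3 with unknown 0), shape and
#' histogram features come from the mask and the original masked
#' intensities, and the per-derived-image first-order and texture families
#' are computed over the nine-filter bank.
#'
#' @param phantom a `phantom` (or list with `image`, `mask`, `spacing`,
#'   `clinical`).
#' @param n_gray_levels texture quantization bins, default 32.
#' @return named numeric vector ordered by [feature_catalogue()]
#'   (length 868).
#' @export
extract_all <- function(phantom, n_gray_levels = 32L) {
  img <- phantom$image; mask <- phantom$mask
  sp <- if (is.null(phantom$spacing)) 1 else phantom$spacing
  cl <- phantom$clinical
  clin <- c(clinical_age = as.numeric(cl$age),
            clinical_hpv_status = switch(cl$hpv_status, positive = 1,
                                         negative = 0, unknown = 0.5),
            clinical_figo_stage = switch(cl$figo_stage, "I" = 1, "II" = 2,
                                         "III/IV" = 3, "unknown" = 0),
            clinical_lymph_node_metastasis = as.numeric(cl$lymph_node_metastasis),
            clinical_lymphovascular_invasion = as.numeric(cl$lymphovascular_invasion),
            clinical_invasion_depth = as.numeric(cl$invasion_depth),
            clinical_chemotherapy = as.numeric(cl$chemotherapy),
            clinical_radiotherapy = as.numeric(cl$radiotherapy))
  out <- c(clin,
           shape_features(mask, sp),
           histogram_features(img[mask != 0]))
  bank <- derive_images(img, sp)
  inside <- mask != 0
  for (kind in derived_image_kinds()) {
    di <- bank[[kind]]
    fo <- first_order_features(di[inside], sp)
    tx <- texture_features(texture_matrices(di, mask, n_gray_levels))
    block <- c(fo, tx)
    names(block) <- paste0(names(block), "__", kind)
    out <- c(out, block)
  }
  bad <- !is.finite(out)
  if (any(bad)) {
    stop("non-finite feature(s): ", paste(names(out)[bad], collapse = ", "))
  }
  out
}

#' Extract features for a cohort of phantoms
#'
#' @param phantoms list of `phantom` objects.
#' @param n_gray_levels texture quantization bins.
#' @return numeric matrix (subjects x features) with catalogue column
#'   names; row names are subject indices.
#' @export
extract_cohort <- function(phantoms, n_gray_levels = 32L) {
  rows <- lapply(phantoms, extract_all, n_gray_levels = n_gray_levels)
  mat <- do.call(rbind, rows)
  rownames(mat) <- seq_along(phantoms)
  mat
}
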
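# Named texture features over the five matrix families. Formula conventions
# follow the de-facto standard radiomics definitions (symmetrised,
# angle-averaged GLCM; run/zone/dependence matrices normalised by their
# totals). Degenerate inputs (a single occupied gray level) use fixed finite
# conventions: entropies 0, correlation-type features 0 -- never NaN/Inf.

safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

#' GLCM feature vector (24 features)
#' @param P symmetric, normalised co-occurrence probability matrix.
#' @return named numeric vector.
#' @export
glcm_features <- function(P) {
  ng <- nrow(P)
  s <- sum(P)
  if (s > 0) P <- P / s
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal / cross-diagonal distributions
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_dif <- 0:(ng - 1)
  p_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), numeric(1))
  hxy <- -sum(P * safe_log2(P))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * safe_log2(pxy))
  hxy2 <- -sum(pxy * safe_log2(pxy))
  hx <- -sum(px * safe_log2(px)); hy <- -sum(py * safe_log2(py))
  da <- sum(k_dif * p_dif)
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  # maximal correlation coefficient
  act <- which(px > 0)
  mcc <- 0
  if (length(act) >= 2) {
    Pa <- P[act, act, drop = FALSE]
    pxa <- px[act]; pya <- py[act]
    Q <- matrix(0, length(act), length(act))
    for (ii in seq_along(act)) {
      Q[ii, ] <- colSums(t(Pa) * Pa[ii, ] / (pxa[ii] * pya))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(min(ev[2], 1), 0))
  }
  c(glcm_Autocorrelation = sum(i * j * P),
    glcm_ClusterProminence = sum((i + j - mux - muy)^4 * P),
    glcm_ClusterShade = sum((i + j - mux - muy)^3 * P),
    glcm_ClusterTendency = sum((i + j - mux - muy)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(p_dif * safe_log2(p_dif)),
    glcm_DifferenceVariance = sum((k_dif - da)^2 * p_dif),
    glcm_Id = sum(P / (1 + abs(i - j))),
    glcm_Idm = sum(P / (1 + (i - j)^2)),
    glcm_Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    glcm_Idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    glcm_JointAverage = mux,
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = hxy,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(k_sum * p_sum),
    glcm_SumEntropy = -sum(p_sum * safe_log2(p_sum)),
    glcm_SumSquares = sum((i - mux)^2 * P))
}

# Shared machinery for GLRLM/GLSZM/GLDM-style (level x size) count matrices.
level_size_features <- function(M, n_pixels, prefix, size_names) {
  nr <- sum(M)
  if (nr == 0) nr <- 1
  ng <- nrow(M); nj <- ncol(M)
  i <- matrix(seq_len(ng), ng, nj)
  j <- matrix(seq_len(nj), ng, nj, byrow = TRUE)
  p <- M / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  ri <- rowSums(M); rj <- colSums(M)
  out <- c(sum(M / j^2) / nr,                 # small emphasis
           sum(M * j^2) / nr,                 # large emphasis
           sum(ri^2) / nr,                    # gray-level non-uniformity
           sum(ri^2) / nr^2,                  # ... normalised
           sum(rj^2) / nr,                    # size non-uniformity
           sum(rj^2) / nr^2,                  # ... normalised
           nr / n_pixels,                     # percentage
           sum(p * (i - mu_i)^2),             # gray-level variance
           sum(p * (j - mu_j)^2),             # size variance
           -sum(p * safe_log2(p)),            # entropy
           sum(M / i^2) / nr,                 # low gray-level emphasis
           sum(M * i^2) / nr,                 # high gray-level emphasis
           sum(M / (i^2 * j^2)) / nr,         # small + low
           sum(M * i^2 / j^2) / nr,           # small + high
           sum(M * j^2 / i^2) / nr,           # large + low
           sum(M * i^2 * j^2) / nr)           # large + high
  names(out) <- paste0(prefix, size_names)
  out
}

#' GLRLM feature vector (16 features)
#' @param M run-length count matrix (levels x run length).
#' @param n_pixels number of masked pixels.
#' @return named numeric vector.
#' @export
glrlm_features <- function(M, n_pixels) {
  v <- level_size_features(M, n_pixels, "glrlm_", c(
    "ShortRunEmphasis", "LongRunEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
    "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
  v
}

#' GLSZM feature vector (16 features)
#' @param M size-zone count matrix (levels x zone size).
#' @param n_pixels number of masked pixels.
#' @return named numeric vector.
#' @export
glszm_features <- function(M, n_pixels) {
  level_size_features(M, n_pixels, "glszm_", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
    "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

#' GLDM feature vector (14 features)
#'
#' The dependence matrix column index is dependence + 1 (so a pixel with no
#' equal-level neighbour sits in column 1), keeping the small/large
#' dependence emphases finite.
#'
#' @param M dependence count matrix (levels x 9).
#' @param n_pixels number of masked pixels.
#' @return named numeric vector.
#' @export
gldm_features <- function(M, n_pixels) {
  v <- level_size_features(M, n_pixels, "gldm_", c(
    "SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "DependenceNonUniformity", "DependenceNonUniformityNormalized",
    "DependencePercentage", "GrayLevelVariance", "DependenceVariance",
    "DependenceEntropy",
    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis"))
  # the 14-feature family drops the normalised gray-level non-uniformity and
  # the (always 1) dependence percentage
  v[setdiff(names(v), c("gldm_GrayLevelNonUniformityNormalized",
                        "gldm_DependencePercentage"))]
}

#' NGTDM feature vector (5 features)
#' @param tab data.frame from [ngtdm_matrix()] with columns `level`, `n`,
#'   `p`, `s`.
#' @return named numeric vector: Coarseness, Contrast, Busyness,
#'   Complexity, Strength.
#' @export
ngtdm_features <- function(tab) {
  act <- tab$p > 0
  pi_ <- tab$p[act]; si <- tab$s[act]; li <- tab$level[act]
  nvp <- sum(tab$n)
  ngp <- sum(act)
  coars <- if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6
  contrast <- 0; busy <- 0; cmplx <- 0; strength <- 0
  if (ngp >= 2) {
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    pp <- outer(pi_, pi_)
    contrast <- sum(pp * dif2) / (ngp * (ngp - 1)) * sum(si) / nvp
    denom <- sum(abs(outer(li * pi_, li * pi_, "-")))
    busy <- if (denom > 0) sum(pi_ * si) / denom else 0
    absdif <- sqrt(dif2)
    psum <- outer(pi_, pi_, "+")
    num <- outer(pi_ * si, pi_ * si, "+")
    cmplx <- sum(absdif * num / psum) / nvp
    strength <- if (sum(si) > 0) sum(psum * dif2) / sum(si) else 0
  }
  c(ngtdm_Coarseness = coars, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busy, ngtdm_Complexity = cmplx,
    ngtdm_Strength = strength)
}

#' All texture features from a texture-matrix set
#'
#' @param tm a `texture_matrix_set` from [texture_matrices()].
#' @return named numeric vector of 24 + 16 + 16 + 14 + 5 = 75 features.
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix_set"))
  c(glcm_features(tm$glcm),
    glrlm_features(tm$glrlm, tm$n_masked),
    glszm_features(tm$glszm, tm$n_masked),
    gldm_features(tm$gldm, tm$n_masked),
    ngtdm_features(tm$ngtdm))
}
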
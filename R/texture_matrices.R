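# Texture-matrix construction on quantized masked images.
#
# The masked intensities are quantized to n_gray_levels equal-width bins;
# a quantized image holds levels 1..n_gray_levels inside the mask and NA
# outside. All five matrix families are computed on that representation:
#  GLCM  - distance-1 pairs in 4 directions, symmetrised, angle-averaged;
#  GLRLM - runs of equal level along the 4 directions, summed;
#  GLSZM - 8-connected zones of equal level, by zone size;
#  GLDM  - per-pixel count of equal-level 8-neighbours (dependence, alpha=0);
#  NGTDM - per-level sums of |level - mean of masked 8-neighbourhood|.

#' Quantize masked intensities to equal-width gray-level bins
#'
#' @param image numeric matrix.
#' @param mask binary matrix (1 = inside region of interest).
#' @param n_gray_levels number of bins (>= 2).
#' @return integer matrix with levels `1..n_gray_levels` inside the mask
#'   and `NA` outside.
#' @export
quantize_image <- function(image, mask, n_gray_levels = 32L) {
  if (!all(dim(image) == dim(mask))) stop("shape mismatch")
  if (n_gray_levels < 2L) stop("n_gray_levels must be >= 2")
  inside <- mask != 0
  if (!any(inside)) stop("mask must contain at least one pixel")
  v <- image[inside]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    q[inside] <- 1L
    return(q)
  }
  width <- (hi - lo) / n_gray_levels
  lev <- pmin(as.integer(floor((v - lo) / width)) + 1L, n_gray_levels)
  q[inside] <- lev
  q
}

# The four distance-1 direction offsets (0 deg, 90 deg, 45 deg, 135 deg in
# matrix (row, col) coordinates).
texture_offsets <- function() {
  list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
}

#' Gray-level co-occurrence matrix
#'
#' @param q quantized image from [quantize_image()].
#' @param n_levels number of gray levels.
#' @param symmetric symmetrise each directional matrix (default TRUE).
#' @param average average the (normalised) directional matrices
#'   (default TRUE). With `average = FALSE` a list of raw count matrices
#'   per direction is returned.
#' @return `n_levels x n_levels` probability matrix, or list of count
#'   matrices.
#' @export
glcm_matrix <- function(q, n_levels, symmetric = TRUE, average = TRUE) {
  n <- nrow(q); m <- ncol(q)
  mats <- lapply(texture_offsets(), function(off) {
    M <- matrix(0, n_levels, n_levels)
    r1 <- max(1L, 1L - off[1]):min(n, n - off[1])
    c1 <- max(1L, 1L - off[2]):min(m, m - off[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- table(factor(a[ok], levels = seq_len(n_levels)),
                   factor(b[ok], levels = seq_len(n_levels)))
      M <- M + matrix(tab, n_levels, n_levels)
    }
    if (symmetric) M <- M + t(M)
    M
  })
  if (!average) return(mats)
  P <- matrix(0, n_levels, n_levels)
  for (M in mats) {
    s <- sum(M)
    if (s > 0) P <- P + M / s
  }
  P / length(mats)
}

#' Gray-level run length matrix
#'
#' Runs of equal gray level along the four directions; mask gaps break
#' runs; the four directional matrices are summed.
#'
#' @param q quantized image.
#' @param n_levels number of gray levels.
#' @return matrix `n_levels x max_run_length` of run counts.
#' @export
glrlm_matrix <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  maxlen <- max(n, m)
  M <- matrix(0, n_levels, maxlen)
  add_line <- function(vals) {
    if (length(vals) == 0L) return()
    r <- rle(ifelse(is.na(vals), -1L, vals))
    keep <- r$values > 0
    for (k in which(keep)) {
      M[r$values[k], r$lengths[k]] <<- M[r$values[k], r$lengths[k]] + 1
    }
  }
  for (i in seq_len(n)) add_line(q[i, ])              # 0 degrees
  for (j in seq_len(m)) add_line(q[, j])              # 90 degrees
  for (s in seq_len(n + m - 1L)) {                    # 45 and 135 degrees
    d1 <- s - m                                        # anti-diagonals
    i1 <- max(1L, d1 + 1L):min(n, s)
    add_line(q[cbind(i1, s - i1 + 1L)])
    i2 <- max(1L, s - m + 1L):min(n, s)               # main diagonals
    add_line(q[cbind(i2, i2 - s + m)])
  }
  # trim empty tail columns (keep at least one column)
  last <- max(1L, max(which(colSums(M) > 0), 1L))
  M[, seq_len(last), drop = FALSE]
}

#' Gray-level size zone matrix
#'
#' 8-connected zones of equal gray level, counted by zone size.
#'
#' @param q quantized image.
#' @param n_levels number of gray levels.
#' @return matrix `n_levels x max_zone_size` of zone counts.
#' @export
glszm_matrix <- function(q, n_levels) {
  sizes_by_level <- zone_sizes(q, n_levels)
  all_sz <- unlist(sizes_by_level, use.names = FALSE)
  maxsz <- if (length(all_sz)) max(all_sz) else 1L
  M <- matrix(0, n_levels, maxsz)
  for (lev in seq_len(n_levels)) {
    sz <- sizes_by_level[[lev]]
    if (length(sz)) {
      t <- tabulate(sz, nbins = maxsz)
      M[lev, ] <- M[lev, ] + t
    }
  }
  M
}

# 8-connected same-level zones; returns list (per level) of zone sizes.
zone_sizes <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  idx <- which(!is.na(q))
  out <- rep(list(integer(0)), n_levels)
  if (length(idx) == 0L) return(out)
  pos <- integer(n * m); pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% n) + 1L
  cl <- ((idx - 1L) %/% n) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + off[1]; c2 <- cl + off[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= m
    j <- (c2[ok] - 1L) * n + r2[ok]
    same <- !is.na(q[j]) & q[j] == q[idx[ok]]
    if (any(same)) {
      edges <- c(edges, rbind(pos[idx[ok][same]], pos[j[same]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lev_of_comp <- q[idx][match(seq_len(comp$no), comp$membership)]
  for (k in seq_len(comp$no)) {
    lv <- lev_of_comp[k]
    out[[lv]] <- c(out[[lv]], comp$csize[k])
  }
  out
}

#' Gray-level dependence matrix
#'
#' For each masked pixel, the dependence is the number of masked
#' 8-neighbours with the same gray level (alpha = 0, Chebyshev distance 1).
#'
#' @param q quantized image.
#' @param n_levels number of gray levels.
#' @return matrix `n_levels x 9` (columns = dependence 0..8, stored 1-based).
#' @export
gldm_matrix <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  dep <- matrix(0L, n, m)
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                   c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    shifted <- shift_na(q, off)
    eq <- !is.na(q) & !is.na(shifted) & q == shifted
    dep <- dep + eq
  }
  M <- matrix(0, n_levels, 9L)
  inside <- !is.na(q)
  tab <- table(factor(q[inside], levels = seq_len(n_levels)),
               factor(dep[inside], levels = 0:8))
  M + matrix(tab, n_levels, 9L)
}

shift_na <- function(q, off) {
  n <- nrow(q); m <- ncol(q)
  out <- matrix(NA_integer_, n, m)
  r1 <- max(1L, 1L + off[1]):min(n, n + off[1])
  c1 <- max(1L, 1L + off[2]):min(m, m + off[2])
  out[r1, c1] <- q[r1 - off[1], c1 - off[2]]
  out
}

#' Neighbourhood gray-tone difference matrix
#'
#' Per gray level i: `n_i` (pixel count), `p_i = n_i / N`, and
#' `s_i = sum over pixels of level i of |i - mean(masked 8-neighbourhood)|`.
#' Pixels with no masked neighbour contribute zero difference.
#'
#' @param q quantized image.
#' @param n_levels number of gray levels.
#' @return data.frame with columns `level`, `n`, `p`, `s`.
#' @export
ngtdm_matrix <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  nb_sum <- matrix(0, n, m)
  nb_cnt <- matrix(0, n, m)
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                   c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    sh <- shift_na(q, off)
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_cnt <- nb_cnt + ok
  }
  inside <- !is.na(q)
  s <- numeric(n_levels); cnt <- numeric(n_levels)
  has_nb <- inside & nb_cnt > 0
  diffs <- abs(q[has_nb] - nb_sum[has_nb] / nb_cnt[has_nb])
  lev <- q[has_nb]
  for (l in seq_len(n_levels)) {
    s[l] <- sum(diffs[lev == l])
  }
  cnt <- tabulate(q[inside], nbins = n_levels)
  data.frame(level = seq_len(n_levels), n = cnt,
             p = cnt / sum(cnt), s = s)
}

#' Compute the full texture-matrix set for a masked derived image
#'
#' @param image numeric matrix (a derived image).
#' @param mask binary matrix.
#' @param n_gray_levels quantization bins, default 32.
#' @return list of class `texture_matrix_set` with `glcm` (probability
#'   matrix), `glrlm`, `glszm`, `gldm` (count matrices), `ngtdm`
#'   (data.frame), `n_gray_levels`, `n_masked`.
#' @export
texture_matrices <- function(image, mask, n_gray_levels = 32L) {
  q <- quantize_image(image, mask, n_gray_levels)
  structure(list(glcm = glcm_matrix(q, n_gray_levels),
                 glrlm = glrlm_matrix(q, n_gray_levels),
                 glszm = glszm_matrix(q, n_gray_levels),
                 gldm = gldm_matrix(q, n_gray_levels),
                 ngtdm = ngtdm_matrix(q, n_gray_levels),
                 n_gray_levels = n_gray_levels,
                 n_masked = sum(mask != 0)),
            class = "texture_matrix_set")
}
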
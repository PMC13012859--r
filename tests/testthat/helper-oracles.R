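# Independent brute-force oracles used across the suite. These deliberately
# re-enumerate pixels/pairs/runs/zones with naive loops, independent of the
# package's vectorised implementations.

# naive GLCM counts for one offset (no symmetrisation)
oracle_glcm_counts <- function(q, n_levels, off) {
  M <- matrix(0, n_levels, n_levels)
  n <- nrow(q); m <- ncol(q)
  for (r in seq_len(n)) for (cl in seq_len(m)) {
    r2 <- r + off[1]; c2 <- cl + off[2]
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m &&
        !is.na(q[r, cl]) && !is.na(q[r2, c2])) {
      M[q[r, cl], q[r2, c2]] <- M[q[r, cl], q[r2, c2]] + 1
    }
  }
  M
}

oracle_glcm_avg <- function(q, n_levels) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  P <- matrix(0, n_levels, n_levels)
  for (off in offs) {
    M <- oracle_glcm_counts(q, n_levels, off)
    M <- M + t(M)
    if (sum(M) > 0) P <- P + M / sum(M)
  }
  P / length(offs)
}

# naive run-length counts: walk every scan line of every direction
oracle_glrlm <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  M <- matrix(0, n_levels, max(n, m))
  runs_of <- function(vals) {
    cur <- NA; len <- 0
    flush <- function() {
      if (!is.na(cur) && len > 0) M[cur, len] <<- M[cur, len] + 1
    }
    for (v in c(vals, NA)) {
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        flush()
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
    }
  }
  for (i in seq_len(n)) runs_of(q[i, ])
  for (j in seq_len(m)) runs_of(q[, j])
  for (s in seq_len(n + m - 1)) {
    vals <- c(); for (i in seq_len(n)) {
      j <- s - i + 1
      if (j >= 1 && j <= m) vals <- c(vals, q[i, j])
    }
    runs_of(vals)
    vals <- c(); for (i in seq_len(n)) {
      j <- i - s + m
      if (j >= 1 && j <= m) vals <- c(vals, q[i, j])
    }
    runs_of(vals)
  }
  last <- max(1, max(which(colSums(M) > 0), 1))
  M[, seq_len(last), drop = FALSE]
}

# naive zone sizes by repeated flood fill (8-connectivity)
oracle_glszm <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  seen <- matrix(FALSE, n, m)
  sizes <- list()
  for (r in seq_len(n)) for (cl in seq_len(m)) {
    if (!is.na(q[r, cl]) && !seen[r, cl]) {
      lev <- q[r, cl]
      stack <- list(c(r, cl)); seen[r, cl] <- TRUE; size <- 0
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if ((dr != 0 || dc != 0) && rr >= 1 && rr <= n && cc >= 1 &&
              cc <= m && !seen[rr, cc] && !is.na(q[rr, cc]) &&
              q[rr, cc] == lev) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
      sizes[[length(sizes) + 1]] <- c(lev, size)
    }
  }
  maxsz <- max(1, vapply(sizes, `[`, numeric(1), 2))
  M <- matrix(0, n_levels, maxsz)
  for (z in sizes) M[z[1], z[2]] <- M[z[1], z[2]] + 1
  M
}

oracle_gldm <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  M <- matrix(0, n_levels, 9)
  for (r in seq_len(n)) for (cl in seq_len(m)) {
    if (is.na(q[r, cl])) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- cl + dc
      if ((dr != 0 || dc != 0) && rr >= 1 && rr <= n && cc >= 1 &&
          cc <= m && !is.na(q[rr, cc]) && q[rr, cc] == q[r, cl]) {
        dep <- dep + 1
      }
    }
    M[q[r, cl], dep + 1] <- M[q[r, cl], dep + 1] + 1
  }
  M
}

oracle_ngtdm <- function(q, n_levels) {
  n <- nrow(q); m <- ncol(q)
  s <- numeric(n_levels); cnt <- numeric(n_levels)
  for (r in seq_len(n)) for (cl in seq_len(m)) {
    if (is.na(q[r, cl])) next
    cnt[q[r, cl]] <- cnt[q[r, cl]] + 1
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- cl + dc
      if ((dr != 0 || dc != 0) && rr >= 1 && rr <= n && cc >= 1 &&
          cc <= m && !is.na(q[rr, cc])) {
        nb <- c(nb, q[rr, cc])
      }
    }
    if (length(nb)) {
      s[q[r, cl]] <- s[q[r, cl]] + abs(q[r, cl] - mean(nb))
    }
  }
  data.frame(level = seq_len(n_levels), n = cnt, p = cnt / sum(cnt), s = s)
}

# brute-force position attention (double loop over the defining sums)
oracle_attention <- function(A, Wb, Wc, Wd, alpha) {
  d <- dim(A); H <- d[1]; W <- d[2]; C <- d[3]
  N <- H * W
  Am <- t(matrix(A, N, C))
  Bm <- Wb %*% Am; Cm <- Wc %*% Am; Dm <- Wd %*% Am
  S <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- numeric(N)
    for (i in seq_len(N)) e[i] <- exp(sum(Bm[, i] * Cm[, j]))
    for (i in seq_len(N)) S[j, i] <- e[i] / sum(e)
  }
  E <- matrix(0, C, N)
  for (j in seq_len(N)) {
    acc <- rep(0, C)
    for (i in seq_len(N)) acc <- acc + S[j, i] * Dm[, i]
    E[, j] <- alpha * acc + Am[, j]
  }
  list(E = array(t(E), c(H, W, C)), S = S)
}

# naive symmetric Hausdorff over boundary pixel sets
oracle_hausdorff <- function(a_mask, b_mask) {
  bnd <- function(m) {
    out <- NULL
    n <- nrow(m); k <- ncol(m)
    for (r in seq_len(n)) for (cl in seq_len(k)) {
      if (m[r, cl] != 0) {
        edge <- r == 1 || r == n || cl == 1 || cl == k ||
          m[r - 1, cl] == 0 || m[r + 1, cl] == 0 ||
          m[r, cl - 1] == 0 || m[r, cl + 1] == 0
        if (edge) out <- rbind(out, c(r, cl))
      }
    }
    out
  }
  A <- bnd(a_mask); B <- bnd(b_mask)
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2))
    }, numeric(1))
  }
  max(max(dmin(A, B)), max(dmin(B, A)))
}

# sliding-window early-stop scan
oracle_early_stop <- function(history, patience, min_delta) {
  n <- length(history)
  if (n <= patience) return(FALSE)
  best <- max(history[1:(n - patience)])
  improved <- FALSE
  for (t in (n - patience + 1):n) {
    if (history[t] >= best + min_delta) improved <- TRUE
  }
  !improved
}

random_quantized <- function(n, m, n_levels, p_mask = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- matrix(sample(seq_len(n_levels), n * m, replace = TRUE), n, m)
  if (p_mask < 1) {
    q[matrix(runif(n * m) > p_mask, n, m)] <- NA_integer_
  }
  q
}

tiny_phantom_config <- function(seed = 1L, noise_sd = 0.1) {
  phantom_config(image_size = 64L, pixel_spacing = 1.0,
                 lesion_diameter_range = c(10, 40),
                 noise_sd = noise_sd, seed = seed)
}
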
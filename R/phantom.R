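#' Configuration for synthetic MRI phantoms
#'
#' A phantom is a single-channel MRI-like slice containing one quasi-elliptical
#' lesion of clinically plausible size (equivalent diameter 10--40 mm by
#' default, the clinical size prior for cervical lesions), plus a paired
#' binary mask, a simulated clinical record and a pathology label.
#'
#' @param image_size pixels per side (square slice), default 256.
#' @param pixel_spacing mm per pixel, default 0.5.
#' @param lesion_diameter_range mm interval for the lesion equivalent
#'   diameter, default `c(10, 40)`.
#' @param noise_sd standard deviation of additive Gaussian background noise
#'   (dimensionless intensity units), default 0.1.
#' @param texture_sd relative amplitude of the correlated lesion texture
#'   (scales with the subtype mean shift), default 0.15.
#' @param subtype_effects list of 8 per-category effect lists, each with
#'   `mean_shift` (intensity offset of the lesion), `corr_len` (texture
#'   correlation length in pixels) and `low_frac` (fraction of lesion area
#'   occupied by low-signal zones). Defaults spread the eight pathological
#'   categories over distinct intensity/texture regimes.
#' @param clinical_coupling numeric in [0,1]; 0 (default) draws clinical
#'   covariates independently of the pathology label, so that
#'   clinical-feature exclusion by downstream selection is expected.
#' @param seed integer seed; every `generate_*` call is deterministic given
#'   the config seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           pixel_spacing = 0.5,
                           lesion_diameter_range = c(10, 40),
                           noise_sd = 0.1,
                           texture_sd = 0.15,
                           subtype_effects = default_subtype_effects(),
                           clinical_coupling = 0,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 1L, image_size >= 64L,
            pixel_spacing > 0, noise_sd >= 0, texture_sd >= 0,
            length(lesion_diameter_range) == 2L,
            clinical_coupling >= 0, clinical_coupling <= 1)
  if (lesion_diameter_range[1] <= 0 ||
      lesion_diameter_range[2] <= lesion_diameter_range[1] ||
      lesion_diameter_range[2] >= image_size * pixel_spacing) {
    stop("lesion_diameter_range must be an ordered positive interval ",
         "strictly inside (0, image_size * pixel_spacing)")
  }
  if (length(subtype_effects) != 8L) {
    stop("subtype_effects must list effects for all 8 categories")
  }
  structure(list(image_size = image_size,
                 pixel_spacing = pixel_spacing,
                 lesion_diameter_range = as.numeric(lesion_diameter_range),
                 noise_sd = noise_sd,
                 texture_sd = texture_sd,
                 subtype_effects = subtype_effects,
                 clinical_coupling = clinical_coupling,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default per-category lesion appearance effects
#'
#' Mean shifts, texture correlation lengths and low-signal-zone fractions
#' for the eight pathological categories. The spread is chosen so that the
#' lesion mean intensity and its texture statistics are label-informative:
#' categories differ by at least 0.2 intensity units in mean shift and by
#' up to a factor ~4 in correlation length.
#'
#' @return list of 8 lists with `mean_shift`, `corr_len`, `low_frac`.
#' @export
default_subtype_effects <- function() {
  shifts <- seq(1.0, 2.4, length.out = 8)
  corr   <- c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5)
  lowfr  <- c(0.00, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35)
  lapply(seq_len(8), function(k) {
    list(mean_shift = shifts[k], corr_len = corr[k], low_frac = lowfr[k])
  })
}

#' Pathology label from three binary pathological variables
#'
#' The eight-way category is the 3-bit binary encoding
#' `category = 4*cell_size + 2*keratinization + histology` where
#' cell_size: 0 = small, 1 = large; keratinization: 0 = keratinizing,
#' 1 = non-keratinizing; histology: 0 = squamous, 1 = adenocarcinoma.
#'
#' @param cell_size,keratinization,histology binary scalars (0/1).
#' @return object of class `pathology_label` with fields `cell_size`,
#'   `keratinization`, `histology`, `category`, `name`.
#' @export
pathology_label <- function(cell_size, keratinization, histology) {
  for (v in list(cell_size, keratinization, histology)) {
    if (length(v) != 1L || !(v %in% c(0, 1))) {
      stop("pathology variables must be binary scalars (0/1)")
    }
  }
  category <- 4L * as.integer(cell_size) + 2L * as.integer(keratinization) +
    as.integer(histology)
  structure(list(cell_size = as.integer(cell_size),
                 keratinization = as.integer(keratinization),
                 histology = as.integer(histology),
                 category = category,
                 name = pathology_category_names()[category + 1L]),
            class = "pathology_label")
}

#' Pathology label from a category code 0--7
#' @param category integer 0--7.
#' @return `pathology_label`.
#' @export
pathology_label_from_category <- function(category) {
  stopifnot(length(category) == 1L, category %in% 0:7)
  category <- as.integer(category)
  pathology_label(cell_size = category %/% 4L,
                  keratinization = (category %/% 2L) %% 2L,
                  histology = category %% 2L)
}

#' Full names of the eight pathological categories
#' @return character vector of length 8, index = category + 1.
#' @export
pathology_category_names <- function() {
  c("Small-cell keratinizing squamous cell carcinoma",
    "Small-cell keratinizing adenocarcinoma",
    "Small-cell non-keratinizing squamous cell carcinoma",
    "Small-cell non-keratinizing adenocarcinoma",
    "Large-cell keratinizing squamous cell carcinoma",
    "Large-cell keratinizing adenocarcinoma",
    "Large-cell non-keratinizing squamous cell carcinoma",
    "Large-cell non-keratinizing adenocarcinoma")
}

# Gaussian-smooth a matrix with an isotropic separable kernel (edge-clamped).
# Used for correlated lesion texture; sigma in pixels.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  sep_filter2(x, k)
}

# Separable filtering with replicate (edge-clamp) padding.
sep_filter2 <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  pad_idx <- function(len) pmin(pmax(seq_len(len + 2L * r) - r, 1L), len)
  xr <- x[pad_idx(n), , drop = FALSE]
  xr <- apply(xr, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  xr <- xr[(r + 1L):(r + n), , drop = FALSE]
  xc <- xr[, pad_idx(m), drop = FALSE]
  xc <- t(apply(xc, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
  xc[, (r + 1L):(r + m), drop = FALSE]
}

# Rasterize a star-shaped lesion: radius r(theta) about (cr, cc), in pixels.
# Returns a logical matrix. Star-convexity keeps the region 4-connected.
rasterize_star <- function(n, cr, cc, radius_fun) {
  rr <- matrix(seq_len(n), n, n) - cr
  cc_ <- matrix(seq_len(n), n, n, byrow = TRUE) - cc
  theta <- atan2(cc_, rr)
  d <- sqrt(rr^2 + cc_^2)
  d <= radius_fun(theta)
}

largest_component_4 <- function(mask) {
  lab <- label_components(mask, connectivity = 4L)
  if (max(lab) <= 1L) return(mask)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

#' Generate one synthetic phantom
#'
#' Deterministic given `config$seed` (plus `index`, which offsets the seed so
#' cohorts get independent draws). The lesion is a random ellipse deformed by
#' low-frequency radial harmonics; lesion intensity is
#' `baseline + mean_shift * (1 + texture_sd * T)` where `T` is a correlated
#' Gaussian field (clipped to +/- 3 SD) with subtype-specific correlation
#' length, minus a low-signal-zone dip on a `low_frac` fraction of the area;
#' the background is `baseline + N(0, noise_sd)`. Because the texture term
#' scales with the mean shift, a zero-noise config with positive mean shift
#' yields every lesion pixel strictly brighter than every background pixel.
#'
#' @param config a [phantom_config()].
#' @param label a [pathology_label()] (or category 0--7).
#' @param index integer draw index (used by [generate_cohort()]).
#' @return object of class `phantom`: list with `image` (matrix), `mask`
#'   (0/1 integer matrix), `spacing`, `clinical` (list of 8 covariates),
#'   `label`.
#' @export
generate_phantom <- function(config, label, index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (!inherits(label, "pathology_label")) {
    label <- pathology_label_from_category(label)
  }
  n <- config$image_size
  sp <- config$pixel_spacing
  eff <- config$subtype_effects[[label$category + 1L]]

  seed_use <- (config$seed + 7919L * as.integer(index)) %% .Machine$integer.max
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed_use)

  rng <- config$lesion_diameter_range
  margin <- 0.06 * diff(rng)
  mask <- NULL
  amp <- 0.08
  for (attempt in 1:8) {
    d_target <- stats::runif(1, rng[1] + margin, rng[2] - margin)
    r0 <- d_target / (2 * sp)                       # equivalent radius, px
    aspect <- stats::runif(1, 0.6, 1.0)
    phi <- stats::runif(1, 0, pi)
    # harmonic boundary deformation, mean-zero
    nh <- 3L
    a_h <- stats::runif(nh, -amp, amp)
    b_h <- stats::runif(nh, -amp, amp)
    # ellipse with equal area: semi-axes r0/sqrt(aspect), r0*sqrt(aspect)
    ra <- r0 / sqrt(aspect); rb <- r0 * sqrt(aspect)
    pad <- max(ra, rb) * (1 + amp * nh) + 2
    if (pad + 1 >= n - pad) {
      # barely fits: centre it
      cr <- (n + 1) / 2; cc <- (n + 1) / 2
    } else {
      cr <- stats::runif(1, pad + 1, n - pad)
      cc <- stats::runif(1, pad + 1, n - pad)
    }
    radius_fun <- function(theta) {
      t2 <- theta - phi
      rell <- (ra * rb) / sqrt((rb * cos(t2))^2 + (ra * sin(t2))^2)
      h <- rep(0, length(theta))
      for (k in seq_len(nh)) {
        h <- h + a_h[k] * cos((k + 1) * theta) + b_h[k] * sin((k + 1) * theta)
      }
      rell * (1 + h)
    }
    m <- rasterize_star(n, cr, cc, radius_fun)
    m <- largest_component_4(m)
    d_real <- 2 * sqrt(sum(m) * sp^2 / pi)
    if (d_real >= rng[1] && d_real <= rng[2] && sum(m) >= 16) {
      mask <- m
      break
    }
    amp <- amp * 0.5                                # tighten deformation, retry
  }
  if (is.null(mask)) stop("could not fit a lesion inside the configured range")

  baseline <- 0
  img <- matrix(baseline, n, n)
  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  }
  # correlated texture field, standardized then clipped to +/- 3
  tex <- matrix(stats::rnorm(n * n), n, n)
  tex <- gaussian_smooth(tex, eff$corr_len)
  tex <- (tex - mean(tex)) / max(stats::sd(tex), 1e-12)
  tex <- pmin(pmax(tex, -3), 3)
  lesion_val <- eff$mean_shift * (1 + config$texture_sd * tex)
  # low-signal zones: darkest quantile of an independent smooth field
  if (eff$low_frac > 0) {
    lz <- gaussian_smooth(matrix(stats::rnorm(n * n), n, n),
                          max(eff$corr_len, 1.5))
    thr <- stats::quantile(lz[mask], eff$low_frac)
    lesion_val[lz <= thr] <- lesion_val[lz <= thr] - 0.3 * eff$mean_shift
  }
  img[mask] <- baseline + lesion_val[mask] +
    if (config$noise_sd > 0) stats::rnorm(sum(mask), 0, config$noise_sd) else 0

  clinical <- sample_clinical_record(label, config$clinical_coupling)

  structure(list(image = img,
                 mask = matrix(as.integer(mask), n, n),
                 spacing = sp,
                 clinical = clinical,
                 label = label),
            class = "phantom")
}

# The 8 clinical covariates; marginals mirror a realistic cervical-cancer
# cohort. With coupling 0 they are independent of the pathology label.
sample_clinical_record <- function(label, coupling = 0) {
  age <- round(min(max(stats::rnorm(1, 51.2, 8.7), 28), 80))
  hpv <- sample(c("positive", "negative", "unknown"), 1,
                prob = c(0.684, 0.079, 0.237))
  figo <- sample(c("I", "II", "III/IV", "unknown"), 1,
                 prob = c(0.421, 0.447, 0.105, 0.026))
  p_ln <- 0.167 + coupling * 0.3 * (label$cell_size - 0.5)
  lnm <- stats::rbinom(1, 1, min(max(p_ln, 0.01), 0.99))
  lvi <- stats::rbinom(1, 1, 0.105)
  depth <- min(max(stats::rnorm(1, 0.54, 0.28), 0), 2)
  chemo <- stats::rbinom(1, 1, 0.772)
  radio <- stats::rbinom(1, 1, 0.509)
  list(age = age, hpv_status = hpv, figo_stage = figo,
       lymph_node_metastasis = lnm, lymphovascular_invasion = lvi,
       invasion_depth = depth, chemotherapy = chemo, radiotherapy = radio)
}

#' Generate a cohort of phantoms
#'
#' @param config a [phantom_config()].
#' @param n number of phantoms (>= 1).
#' @param class_probabilities probability vector over the 8 categories
#'   (non-negative, sums to 1); zero-probability classes are supported so
#'   that absent-category situations can be simulated.
#' @return list of `phantom` objects.
#' @export
generate_cohort <- function(config, n,
                            class_probabilities = rep(1 / 8, 8)) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(n) != 1L || n < 1) stop("n must be >= 1")
  p <- as.numeric(class_probabilities)
  if (length(p) != 8L) stop("class_probabilities must have length 8")
  if (any(p < 0)) stop("class probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("class probabilities must sum to 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  cats <- sample(0:7, n, replace = TRUE, prob = p)
  lapply(seq_len(n), function(i) {
    generate_phantom(config, pathology_label_from_category(cats[i]), index = i)
  })
}

#' Equivalent diameter of a binary mask
#'
#' `d = 2 * sqrt(area * spacing^2 / pi)` in mm.
#' @param mask binary matrix.
#' @param spacing mm per pixel.
#' @return diameter in mm.
#' @export
equivalent_diameter <- function(mask, spacing) {
  2 * sqrt(sum(mask != 0) * spacing^2 / pi)
}

# Connected-component labelling of a logical matrix (4- or 8-connectivity)
# via igraph components on the pixel adjacency graph.
label_components <- function(mask, connectivity = 4L) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  pos <- matrix(0L, n * m, 1)
  pos[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  r <- ((idx - 1L) %% n) + 1L
  cl <- ((idx - 1L) %/% n) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cl + o[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= m
    j <- (c2[ok] - 1L) * n + r2[ok]
    keep <- mask[j]
    if (any(keep)) {
      edges <- c(edges, rbind(pos[idx[ok][keep]], pos[j[keep]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
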
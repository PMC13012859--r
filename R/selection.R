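# Biomarker selection: standardisation, the three-way ranking ensemble
# (forest importance / ANOVA F / recursive feature elimination),
# cross-validated feature-count search, importance cutoff, and the
# correlation/cluster report.

#' Standardize a feature matrix to zero mean and unit variance
#'
#' Fits on the supplied (training) matrix; the returned scaler can be
#' applied to held-out data so no test-set statistics leak into training.
#' Constant columns cannot be standardized and are dropped with a warning.
#'
#' @param mat numeric matrix (subjects x features) with column names.
#' @return list of class `feature_scaler` with `matrix` (standardized),
#'   `center`, `scale`, `dropped`.
#' @export
standardize_features <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  ctr <- colMeans(mat)
  sdv <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[sdv == 0 | !is.finite(sdv)]
  if (length(dropped)) {
    warning("dropping constant column(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  keep <- setdiff(colnames(mat), dropped)
  out <- scale(mat[, keep, drop = FALSE], center = ctr[keep],
               scale = sdv[keep])
  structure(list(matrix = out, center = ctr[keep], scale = sdv[keep],
                 dropped = dropped),
            class = "feature_scaler")
}

#' Apply a fitted scaler to new data
#' @param scaler a `feature_scaler`.
#' @param mat matrix with (at least) the scaler's columns.
#' @return standardized matrix restricted to the scaler's columns.
#' @export
apply_scaler <- function(scaler, mat) {
  stopifnot(inherits(scaler, "feature_scaler"))
  scale(mat[, names(scaler$center), drop = FALSE],
        center = scaler$center, scale = scaler$scale)
}

# Vectorised one-way ANOVA F statistic per feature column.
anova_f_stats <- function(mat, labels) {
  labels <- as.factor(labels)
  g <- nlevels(labels)
  n <- nrow(mat)
  grand <- colMeans(mat)
  ssb <- 0; ssw <- 0
  for (lv in levels(labels)) {
    sub <- mat[labels == lv, , drop = FALSE]
    nk <- nrow(sub)
    mk <- colMeans(sub)
    ssb <- ssb + nk * (mk - grand)^2
    ssw <- ssw + colSums(sweep(sub, 2, mk)^2)
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  f <- msb / msw
  f[msw == 0 & msb == 0] <- 0
  f[msw == 0 & msb > 0] <- Inf
  f
}

#' Rank features by one of the three selection methods
#'
#' \describe{
#'   \item{model_importance}{impurity importance from a seeded random
#'     forest.}
#'   \item{anova_f}{per-feature one-way ANOVA F statistic across classes.}
#'   \item{rfe}{recursive feature elimination: refit a forest, drop the
#'     least important 10\% of remaining features, repeat; features are
#'     scored by survival (later elimination = higher score), survivors of
#'     the final round by their final importance.}
#' }
#' Scores are normalised to sum to 1 over the full ranking.
#'
#' @param mat standardized feature matrix with column names.
#' @param labels class labels (>= 2 classes present).
#' @param method one of `"model_importance"`, `"anova_f"`, `"rfe"`.
#' @param seed integer seed for the forest-based methods.
#' @param num_trees forest size, default 500 (importance estimates need
#'   larger forests than prediction).
#' @details The forest-based rankings use variable-selection settings
#'   rather than prediction defaults: `mtry = p/3` and terminal nodes of
#'   at least `n/10` samples, which concentrate splits (and hence impurity
#'   importance) on genuinely informative features when most features are
#'   noise.
#' @return data.frame with `name`, `score` (descending), `rank`.
#' @export
rank_features <- function(mat, labels,
                          method = c("model_importance", "anova_f", "rfe"),
                          seed = 1L, num_trees = 500L) {
  method <- match.arg(method)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes to rank features")
  nm <- colnames(mat)
  sel_forest <- function(x, seed_use) {
    ranger::ranger(x = x, y = labels, num.trees = num_trees,
                   importance = "impurity",
                   mtry = max(1L, floor(ncol(x) / 3)),
                   min.node.size = max(5L, floor(nrow(x) / 10)),
                   seed = seed_use, num.threads = 1L)
  }
  if (method == "anova_f") {
    f <- anova_f_stats(mat, labels)
    f[!is.finite(f)] <- max(f[is.finite(f)], 1) * 10
    sc <- f
  } else if (method == "model_importance") {
    fit <- sel_forest(mat, seed)
    sc <- fit$variable.importance[nm]
  } else {
    remaining <- nm
    elim_round <- stats::setNames(rep(0L, length(nm)), nm)
    round <- 0L
    final_imp <- NULL
    while (length(remaining) > 1L) {
      round <- round + 1L
      fit <- sel_forest(mat[, remaining, drop = FALSE], seed + round)
      imp <- fit$variable.importance
      ndrop <- max(1L, floor(0.1 * length(remaining)))
      if (length(remaining) - ndrop < 1L) ndrop <- length(remaining) - 1L
      drop_nm <- names(sort(imp))[seq_len(ndrop)]
      elim_round[drop_nm] <- round
      remaining <- setdiff(remaining, drop_nm)
      final_imp <- imp
    }
    elim_round[remaining] <- round + 1L
    # score: elimination round, ties within the last survivors broken by
    # final importance
    sc <- elim_round + 0.5 * rank(replace(
      stats::setNames(rep(0, length(nm)), nm)[nm],
      names(final_imp), final_imp)) / (length(nm) + 1)
    sc <- sc[nm]
  }
  sc <- pmax(as.numeric(sc), 0)
  if (sum(sc) > 0) sc <- sc / sum(sc)
  ord <- order(sc, decreasing = TRUE)
  data.frame(name = nm[ord], score = sc[ord], rank = seq_along(nm),
             row.names = NULL)
}

#' Ensemble ranking by mean reciprocal rank over the three methods
#'
#' @param mat standardized feature matrix.
#' @param labels class labels.
#' @param seed seed for the forest-based methods.
#' @param num_trees forest size.
#' @return list with `ensemble` (data.frame `name`, `score`, `rank`;
#'   score = mean reciprocal rank, normalised to sum 1) and `per_method`
#'   (list of the three rankings).
#' @export
ensemble_rank <- function(mat, labels, seed = 1L, num_trees = 200L) {
  methods <- c("model_importance", "anova_f", "rfe")
  per <- lapply(methods, function(m) {
    rank_features(mat, labels, m, seed = seed, num_trees = num_trees)
  })
  names(per) <- methods
  nm <- colnames(mat)
  mrr <- rep(0, length(nm)); names(mrr) <- nm
  for (r in per) {
    mrr[r$name] <- mrr[r$name] + 1 / r$rank
  }
  mrr <- mrr / length(per)
  mrr <- mrr / sum(mrr)
  ord <- order(mrr, decreasing = TRUE)
  list(ensemble = data.frame(name = nm[ord], score = as.numeric(mrr[ord]),
                             rank = seq_along(nm), row.names = NULL),
       per_method = per)
}

# Stratified k-fold assignment.
stratified_folds <- function(labels, k, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Cross-validated search for the optimal feature count
#'
#' For each candidate k the top-k ensemble-ranked features are scored by
#' k-fold cross-validated forest accuracy; the chosen count is the smallest
#' k whose mean score is within one standard error of the best (so the
#' curve's plateau, not its noisy peak, decides).
#'
#' @param mat standardized feature matrix.
#' @param labels class labels.
#' @param count_grid candidate feature counts, default `seq(5, 100, by 5)`.
#' @param cv_folds folds, default 5.
#' @param cv_repeats independent fold repartitions averaged per k, default
#'   3 (repeated cross-validation smooths the quantisation noise of small
#'   folds, which otherwise drives the one-standard-error rule toward lucky
#'   spikes).
#' @param seed integer seed.
#' @param num_trees forest size for the scoring model, default 100.
#' @return list with `chosen_count`, `cv_score_by_count` (data.frame `k`,
#'   `mean`, `se`), and `ranking` (the ensemble ranking used).
#' @export
choose_feature_count <- function(mat, labels,
                                 count_grid = seq(5L, 100L, by = 5L),
                                 cv_folds = 5L, cv_repeats = 3L,
                                 seed = 1L, num_trees = 100L) {
  if (length(count_grid) == 0L) stop("count_grid must be non-empty")
  count_grid <- sort(unique(pmin(count_grid, ncol(mat))))
  ens <- ensemble_rank(mat, labels, seed = seed)
  ranking <- ens$ensemble
  labels <- as.factor(as.character(labels))
  folds <- lapply(seq_len(cv_repeats), function(rep) {
    stratified_folds(labels, cv_folds, seed = seed + 100L * rep)
  })
  res <- lapply(count_grid, function(k) {
    feats <- ranking$name[seq_len(k)]
    accs <- unlist(lapply(seq_len(cv_repeats), function(rep) {
      fold <- folds[[rep]]
      vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        fit <- ranger::ranger(x = mat[tr, feats, drop = FALSE],
                              y = labels[tr], num.trees = num_trees,
                              seed = seed + 10L * rep + f,
                              num.threads = 1L)
        pred <- stats::predict(
          fit, data = mat[!tr, feats, drop = FALSE])$predictions
        mean(pred == labels[!tr])
      }, numeric(1))
    }))
    c(mean = mean(accs), se = stats::sd(accs) / sqrt(length(accs)))
  })
  tab <- data.frame(k = count_grid,
                    mean = vapply(res, `[[`, numeric(1), "mean"),
                    se = vapply(res, `[[`, numeric(1), "se"))
  best <- which.max(tab$mean)
  thr <- tab$mean[best] - tab$se[best]
  chosen <- tab$k[which(tab$mean >= thr)[1]]
  list(chosen_count = chosen, cv_score_by_count = tab, ranking = ranking)
}

#' Keep features above an importance cutoff, capped at a maximum
#'
#' @param ranking data.frame from [rank_features()] or
#'   [ensemble_rank()]`$ensemble` (normalised scores).
#' @param cutoff minimum normalised score, default 0.01.
#' @param max_keep cap on the number of retained features, default 30.
#' @return list of class `selection_result` with `selected_names`,
#'   `importance_scores`, `chosen_count`.
#' @export
apply_cutoff <- function(ranking, cutoff = 0.01, max_keep = 30L) {
  keep <- ranking$score >= cutoff
  n_keep <- min(sum(keep), max_keep)
  sel <- ranking[seq_len(nrow(ranking)) <= n_keep & keep, , drop = FALSE]
  structure(list(selected_names = sel$name,
                 importance_scores = stats::setNames(sel$score, sel$name),
                 chosen_count = nrow(sel)),
            class = "selection_result")
}

#' Pearson correlation and hierarchical clustering of selected features
#'
#' Average-linkage clustering on the distance `1 - |r|`; the returned leaf
#' order is the canonical ordering for a correlation heatmap.
#'
#' @param mat feature matrix restricted to the selected features (>= 2
#'   non-constant columns).
#' @return list with `correlation` (matrix), `order` (leaf order of the
#'   dendrogram), `hclust` (the tree), `excluded` (zero-variance columns).
#' @export
correlation_cluster_report <- function(mat) {
  sdv <- apply(mat, 2, stats::sd)
  excluded <- colnames(mat)[sdv == 0]
  if (length(excluded)) {
    warning("excluding zero-variance feature(s): ",
            paste(excluded, collapse = ", "))
  }
  mat <- mat[, sdv > 0, drop = FALSE]
  if (ncol(mat) < 2L) stop("need at least 2 non-constant features")
  r <- stats::cor(mat)
  hc <- stats::hclust(stats::as.dist(1 - abs(r)), method = "average")
  list(correlation = r, order = hc$order, hclust = hc, excluded = excluded)
}
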
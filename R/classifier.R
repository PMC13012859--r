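# Pathological typing: 3-bit label encoding, SMOTE balancing, grid-searched
# classifiers (random forest / gradient boosting / SVM / multinomial
# logistic regression), and confusion-matrix / ROC evaluation.

#' Encode the three binary pathological variables as a category 0--7
#'
#' `category = 4*cell_size + 2*keratinization + histology`; the mapping to
#' full category names is bijective (see [pathology_category_names()]).
#'
#' @param cell_size,keratinization,histology binary vectors (0/1).
#' @return integer vector of categories 0--7.
#' @export
encode_pathology <- function(cell_size, keratinization, histology) {
  for (v in list(cell_size, keratinization, histology)) {
    if (!all(v %in% c(0, 1))) stop("pathology variables must be binary")
  }
  as.integer(4 * cell_size + 2 * keratinization + histology)
}

#' SMOTE oversampling of minority classes
#'
#' Every present class is brought up to the majority count by synthesising
#' new rows as convex combinations `x + u * (nn - x)` of a class member and
#' one of its k nearest same-class neighbours (u uniform on [0,1]).
#' Original rows are preserved verbatim. Intended for training folds only.
#'
#' @param mat numeric feature matrix.
#' @param labels class labels (every present class needs >= 2 members).
#' @param k neighbours to sample from, default 5 (reduced automatically for
#'   tiny classes).
#' @param seed integer seed.
#' @return list with `matrix`, `labels`, `synthetic` (logical flag per
#'   row).
#' @export
smote_balance <- function(mat, labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("class(es) with a single member cannot be oversampled: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  target <- max(tab)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  new_rows <- list(); new_labs <- character(0)
  for (cls in names(tab)) {
    need <- target - tab[[cls]]
    if (need == 0) next
    idx <- which(labels == cls)
    sub <- mat[idx, , drop = FALSE]
    kk <- min(k, length(idx) - 1L)
    d2 <- as.matrix(stats::dist(sub))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(kk)]))
    picks <- sample(length(idx), need, replace = TRUE)
    for (t in seq_len(need)) {
      a <- picks[t]
      b <- nn[a, sample(kk, 1)]
      u <- stats::runif(1)
      new_rows[[length(new_rows) + 1L]] <- sub[a, ] + u * (sub[b, ] - sub[a, ])
      new_labs <- c(new_labs, cls)
    }
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    colnames(add) <- colnames(mat)
    list(matrix = rbind(mat, add), labels = c(labels, new_labs),
         synthetic = c(rep(FALSE, nrow(mat)), rep(TRUE, nrow(add))))
  } else {
    list(matrix = mat, labels = labels, synthetic = rep(FALSE, nrow(mat)))
  }
}

#' Classifier specification with a hyperparameter grid
#'
#' Default grids: random forest over n_estimators (50, 100, 200, 300) x
#' max_depth (none, 10, 20, 30) x min_samples_split (2, 5, 10); gradient
#' boosting over rounds/depth/learning rate; RBF SVM over cost/gamma;
#' multinomial logistic regression over the ridge decay.
#'
#' @param family one of `"random_forest"`, `"gradient_boosting"`, `"svm"`,
#'   `"logistic_regression"`.
#' @param grid named list of candidate values; NULL uses the family
#'   default.
#' @param cv_folds folds for the grid search, default 5.
#' @param seed integer seed.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "gradient_boosting",
                                       "svm", "logistic_regression"),
                            grid = NULL, cv_folds = 5L, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      random_forest = list(n_estimators = c(50L, 100L, 200L, 300L),
                           max_depth = c(0L, 10L, 20L, 30L),   # 0 = none
                           min_samples_split = c(2L, 5L, 10L)),
      gradient_boosting = list(nrounds = c(50L, 100L),
                               max_depth = c(3L, 6L),
                               eta = c(0.1, 0.3)),
      svm = list(cost = c(0.1, 1, 10), gamma_scale = c(0.5, 1, 2)),
      logistic_regression = list(decay = c(0, 0.01, 0.1)))
  }
  structure(list(family = family, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

fit_one <- function(family, params, x, y, seed) {
  y <- as.factor(as.character(y))
  if (family == "random_forest") {
    fit <- ranger::ranger(x = x, y = y,
                          num.trees = params$n_estimators,
                          max.depth = params$max_depth,
                          min.node.size = params$min_samples_split,
                          probability = TRUE, seed = seed,
                          num.threads = 1L)
    list(family = family, fit = fit, classes = levels(y))
  } else if (family == "gradient_boosting") {
    yi <- as.integer(y) - 1L
    fit <- xgboost::xgboost(data = as.matrix(x), label = yi,
                            nrounds = params$nrounds,
                            max_depth = params$max_depth,
                            eta = params$eta,
                            objective = "multi:softprob",
                            num_class = nlevels(y),
                            nthread = 1L, verbose = 0)
    list(family = family, fit = fit, classes = levels(y))
  } else if (family == "svm") {
    gam <- params$gamma_scale / ncol(x)
    fit <- e1071::svm(x = x, y = y, cost = params$cost, gamma = gam,
                      kernel = "radial", probability = TRUE)
    list(family = family, fit = fit, classes = levels(y))
  } else {
    df <- data.frame(.y = y, x, check.names = FALSE)
    fit <- nnet::multinom(.y ~ ., data = df, decay = params$decay,
                          maxit = 200, trace = FALSE)
    list(family = family, fit = fit, classes = levels(y))
  }
}

predict_scores <- function(model, x) {
  cls <- model$classes
  if (model$family == "random_forest") {
    p <- stats::predict(model$fit, data = x)$predictions
  } else if (model$family == "gradient_boosting") {
    p <- stats::predict(model$fit, as.matrix(x))
    p <- matrix(p, nrow = nrow(x), byrow = TRUE)
    colnames(p) <- cls
  } else if (model$family == "svm") {
    pr <- stats::predict(model$fit, x, probability = TRUE)
    p <- attr(pr, "probabilities")[, cls, drop = FALSE]
  } else {
    df <- data.frame(x, check.names = FALSE)
    p <- stats::predict(model$fit, newdata = df, type = "probs")
    if (is.null(dim(p))) {  # binary multinom returns a vector
      p <- cbind(1 - p, p)
      colnames(p) <- cls
    }
  }
  p <- as.matrix(p)
  if (is.null(colnames(p))) colnames(p) <- cls
  p[, cls, drop = FALSE]
}

predict_class <- function(model, x) {
  p <- predict_scores(model, x)
  model$classes[max.col(p, ties.method = "first")]
}

#' Grid-searched classifier fit
#'
#' Exhaustive evaluation of the parameter grid by stratified k-fold
#' cross-validation (selection metric: macro F1), refit on the full
#' training data at the best parameters.
#'
#' @param mat training feature matrix (typically SMOTE-balanced).
#' @param labels training labels (>= 2 classes).
#' @param spec a [classifier_spec()].
#' @return list of class `fitted_classifier` with `model`, `best_params`,
#'   `cv_table` (one row per grid point with mean macro-F1), `classes`.
#' @export
fit_with_grid <- function(mat, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes")
  grid_df <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  fold <- stratified_folds(labels, spec$cv_folds, seed = spec$seed)
  cv_scores <- numeric(nrow(grid_df))
  for (gi in seq_len(nrow(grid_df))) {
    params <- as.list(grid_df[gi, , drop = FALSE])
    f1s <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      m <- fit_one(spec$family, params, mat[tr, , drop = FALSE],
                   labels[tr], seed = spec$seed + f)
      pred <- predict_class(m, mat[!tr, , drop = FALSE])
      evaluate_predictions(labels[!tr], pred)$macro_f1
    }, numeric(1))
    cv_scores[gi] <- mean(f1s, na.rm = TRUE)
  }
  best <- which.max(cv_scores)
  best_params <- as.list(grid_df[best, , drop = FALSE])
  model <- fit_one(spec$family, best_params, mat, labels, seed = spec$seed)
  structure(list(model = model, best_params = best_params,
                 cv_table = cbind(grid_df, macro_f1 = cv_scores),
                 classes = model$classes),
            class = "fitted_classifier")
}

# Confusion-based metrics from true/predicted label vectors. The label
# space is the union of training classes and observed test labels, so
# classes absent from training contribute support with zero recall.
evaluate_predictions <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  support <- rowSums(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- support > 0
  list(confusion_matrix = unclass(cm),
       accuracy = sum(tp) / length(truth),
       macro_precision = mean(prec[present]),
       macro_recall = mean(rec[present]),
       macro_f1 = mean(f1[present]),
       per_class = data.frame(class = classes, precision = prec,
                              recall = rec, f1 = f1, support = support,
                              row.names = NULL))
}

#' Evaluate a fitted classifier on a test set
#'
#' Per-class precision/recall/F1 are computed one-vs-rest from the
#' confusion matrix; macro averages run over classes with test support.
#' Test classes absent from training are scored (their recall is
#' necessarily 0 -- the model cannot predict a class it never saw).
#'
#' @param fitted a `fitted_classifier`.
#' @param mat test feature matrix.
#' @param labels test labels.
#' @return list of class `evaluation_report`: confusion matrix, accuracy,
#'   macro precision/recall/F1, per-class table, and one-vs-rest ROC
#'   summaries (see [roc_curves()]).
#' @export
evaluate <- function(fitted, mat, labels) {
  stopifnot(inherits(fitted, "fitted_classifier"))
  if (length(labels) == 0L) stop("empty test set")
  classes <- sort(unique(c(fitted$classes, as.character(labels))))
  pred <- predict_class(fitted$model, mat)
  rep <- evaluate_predictions(labels, pred, classes = classes)
  scores <- predict_scores(fitted$model, mat)
  rep$roc <- roc_curves(scores, labels)
  class(rep) <- "evaluation_report"
  rep
}

#' F1 score from precision and recall (harmonic mean)
#'
#' @param precision,recall values on the same scale (fractions or
#'   percentages).
#' @return F1 on that scale.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' One-vs-rest ROC curves and AUCs
#'
#' AUC by the trapezoidal rule over the empirical ROC with tied scores
#' grouped; constant scores give AUC 0.5. Classes without both a positive
#' and a negative test case get `NA` AUC (flagged, not fabricated).
#'
#' @param scores matrix (cases x classes) of class scores, with class
#'   column names.
#' @param labels true labels.
#' @return list per class with `fpr`, `tpr`, `auc`.
#' @export
roc_curves <- function(scores, labels) {
  labels <- as.character(labels)
  out <- list()
  for (cls in colnames(scores)) {
    y <- as.integer(labels == cls)
    s <- scores[, cls]
    np <- sum(y); nn <- sum(1 - y)
    if (np == 0 || nn == 0) {
      out[[cls]] <- list(fpr = NA_real_, tpr = NA_real_, auc = NA_real_)
      next
    }
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(y == 1 & s >= t) / np, numeric(1))
    fpr <- vapply(thr, function(t) sum(y == 0 & s >= t) / nn, numeric(1))
    fpr <- c(0, fpr); tpr <- c(0, tpr)
    if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
      fpr <- c(fpr, 1); tpr <- c(tpr, 1)
    }
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    out[[cls]] <- list(fpr = fpr, tpr = tpr, auc = auc)
  }
  out
}
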
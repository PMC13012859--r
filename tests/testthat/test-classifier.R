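make_classes <- function(n_per = 30, k = 3, effect = 2, p = 10, seed = 1) {
  set.seed(seed)
  y <- rep(seq_len(k) - 1, each = n_per)
  X <- matrix(rnorm(length(y) * p), length(y), p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  for (cls in seq_len(k) - 1) {
    X[y == cls, cls + 1] <- X[y == cls, cls + 1] + effect
  }
  list(X = X, y = y)
}

test_that("pathology encoding is the exact 3-bit map", {
  expect_equal(encode_pathology(0, 0, 0), 0L)
  expect_equal(encode_pathology(1, 1, 0), 6L)
  expect_equal(encode_pathology(1, 0, 0), 4L)
  grid <- expand.grid(cs = 0:1, ke = 0:1, hi = 0:1)
  cats <- encode_pathology(grid$cs, grid$ke, grid$hi)
  expect_setequal(cats, 0:7)
  expect_error(encode_pathology(2, 0, 0), "binary")
})

test_that("SMOTE balances classes by convex same-class interpolation", {
  set.seed(34)
  X <- rbind(matrix(rnorm(50 * 3, 0), 50, 3),
             matrix(rnorm(10 * 3, 5), 10, 3))
  colnames(X) <- c("a", "b", "c")
  y <- c(rep("A", 50), rep("B", 10))
  out <- smote_balance(X, y, seed = 2)
  expect_equal(unname(table(out$labels)["A"]), 50)
  expect_equal(unname(table(out$labels)["B"]), 50)
  expect_identical(out$matrix[1:60, ], X)           # originals verbatim
  # synthetic B rows lie on segments between B members: inside the B
  # bounding box along every coordinate
  synth <- out$matrix[out$synthetic, , drop = FALSE]
  for (j in 1:3) {
    expect_gte(min(synth[, j]), min(X[51:60, j]) - 1e-9)
    expect_lte(max(synth[, j]), max(X[51:60, j]) + 1e-9)
  }
  # already balanced input is a no-op
  noop <- smote_balance(X[1:20, ], rep(c("A", "B"), each = 10), seed = 3)
  expect_identical(noop$matrix, X[1:20, ])
  expect_error(smote_balance(X[1:11, ], c(rep("A", 10), "B")), "single")
})

test_that("grid search evaluates the documented grid and refits the best", {
  d <- make_classes(n_per = 20, k = 2, seed = 35)
  spec1 <- classifier_spec("random_forest",
                           grid = list(n_estimators = 50L, max_depth = 0L,
                                       min_samples_split = 2L),
                           cv_folds = 3, seed = 1)
  fit1 <- fit_with_grid(d$X, d$y, spec1)
  expect_equal(nrow(fit1$cv_table), 1L)
  expect_equal(fit1$best_params$n_estimators, 50L)

  default_grid <- classifier_spec("random_forest")$grid
  expect_equal(prod(lengths(default_grid)), 48L)    # 4 x 4 x 3
  expect_setequal(default_grid$n_estimators, c(50L, 100L, 200L, 300L))
  expect_setequal(default_grid$max_depth, c(0L, 10L, 20L, 30L))
  expect_setequal(default_grid$min_samples_split, c(2L, 5L, 10L))

  # linearly separable two-class toy reaches CV macro-F1 = 1 somewhere
  sep <- make_classes(n_per = 25, k = 2, effect = 10, seed = 36)
  fit2 <- fit_with_grid(sep$X, sep$y,
                        classifier_spec("random_forest",
                                        grid = list(n_estimators = c(50L, 100L),
                                                    max_depth = 0L,
                                                    min_samples_split = 2L),
                                        cv_folds = 5, seed = 2))
  expect_equal(max(fit2$cv_table$macro_f1), 1)
})

test_that("evaluation reproduces hand confusion arithmetic", {
  truth <- c(rep("pos", 12), rep("neg", 8))
  pred <- c(rep("pos", 8), rep("neg", 4), rep("pos", 2), rep("neg", 6))
  # per-class pos: TP=8, FP=2, FN=4 -> precision 0.8, recall 2/3, F1 8/11
  r <- crfeseg:::evaluate_predictions(truth, pred)
  pc <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pc$precision, 0.8)
  expect_equal(pc$recall, 2 / 3)
  expect_equal(pc$f1, 8 / 11)
  expect_equal(r$accuracy, 14 / 20)

  perfect <- crfeseg:::evaluate_predictions(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
})

test_that("the harmonic-mean F1 identity holds over random confusions", {
  expect_equal(f1_score(87.45, 86.38), 86.91, tolerance = 0.005)
  set.seed(37)
  for (i in 1:100) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0 || tp == 0) next
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(f1_score(prec, rec), 2 * tp / (2 * tp + fp + fn),
                 tolerance = 1e-12)
  }
})

test_that("classes absent from training are never predicted", {
  d <- make_classes(n_per = 25, k = 3, effect = 3, seed = 38)
  train_keep <- d$y != 2
  fit <- fit_with_grid(d$X[train_keep, ], d$y[train_keep],
                       classifier_spec("random_forest",
                                       grid = list(n_estimators = 100L,
                                                   max_depth = 0L,
                                                   min_samples_split = 2L),
                                       cv_folds = 3, seed = 4))
  ev <- evaluate(fit, d$X, d$y)
  pc2 <- ev$per_class[ev$per_class$class == "2", ]
  expect_equal(pc2$recall, 0)
  expect_equal(ev$confusion_matrix["2", "2"], 0)
})

test_that("ROC curves obey their symmetries and null behaviour", {
  y <- rep(c("a", "b"), each = 100)
  s_perfect <- cbind(a = as.numeric(y == "a"), b = as.numeric(y == "b"))
  rc <- roc_curves(s_perfect, y)
  expect_equal(rc$a$auc, 1)
  set.seed(39)
  s_null <- cbind(a = runif(2000), b = runif(2000))
  y2 <- sample(c("a", "b"), 2000, replace = TRUE)
  rn <- roc_curves(s_null, y2)
  expect_lt(abs(rn$a$auc - 0.5), 0.05)
  # reversing scores flips the AUC
  s <- cbind(a = rnorm(200), b = rnorm(200))
  y3 <- rep(c("a", "b"), 100)
  a1 <- roc_curves(s, y3)$a$auc
  a2 <- roc_curves(-s, y3)$a$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-10)
  # constant scores: chance AUC
  rc0 <- roc_curves(cbind(a = rep(0.5, 100), b = rep(0.5, 100)),
                    rep(c("a", "b"), 50))
  expect_equal(rc0$a$auc, 0.5)
  # cross-check against an established implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::roc(response = y3, predictor = s[, "a"], levels = c("b", "a"),
                    direction = "<", quiet = TRUE)
    expect_equal(a1, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  }
})

test_that("multinomial logistic and SVM families fit and score", {
  d <- make_classes(n_per = 20, k = 2, effect = 3, seed = 40)
  for (fam in c("logistic_regression", "svm")) {
    fit <- fit_with_grid(d$X, d$y,
                         classifier_spec(fam,
                                         grid = if (fam == "svm") {
                                           list(cost = 1, gamma_scale = 1)
                                         } else list(decay = 0.01),
                                         cv_folds = 3, seed = 5))
    ev <- evaluate(fit, d$X, d$y)
    expect_gt(ev$accuracy, 0.8)
    sc <- crfeseg:::predict_scores(fit$model, d$X)
    expect_equal(dim(sc), c(40L, 2L))
    expect_equal(unname(rowSums(sc)), rep(1, 40), tolerance = 1e-6)
  }
})
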
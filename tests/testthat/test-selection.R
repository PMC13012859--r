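make_planted <- function(n = 80, p_noise = 45, n_signal = 5, effect = 1.5,
                         seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * (p_noise + n_signal)), n)
  for (k in seq_len(n_signal)) X[y == 1, k] <- X[y == 1, k] + effect
  colnames(X) <- c(paste0("signal", seq_len(n_signal)),
                   paste0("noise", seq_len(p_noise)))
  list(X = X, y = y)
}

test_that("standardization gives exact moments and a reusable scaler", {
  m <- cbind(a = c(2, 4), b = c(0, 10))
  s <- standardize_features(m)
  expect_equal(unname(s$matrix[, "a"]), c(-1, 1) / sqrt(2))
  set.seed(28)
  X <- matrix(rnorm(20 * 50, 5, 2), 20, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  sc <- standardize_features(X)
  expect_lt(max(abs(colMeans(sc$matrix))), 1e-8)
  expect_lt(max(abs(apply(sc$matrix, 2, stats::var) - 1)), 1e-6)
  expect_equal(apply_scaler(sc, X), sc$matrix, ignore_attr = TRUE)
  Xc <- cbind(X, const = rep(1, 20))
  expect_warning(standardize_features(Xc), "constant")
})

test_that("ANOVA-F ranking matches base R and hand computation", {
  # hand case: {1,2,3} vs {4,5,6} -> F = 13.5
  mat <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
                dimnames = list(NULL, "x"))
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(unname(crfeseg:::anova_f_stats(mat, y)), 13.5)
  # vectorised statistic equals oneway.test with equal variances
  set.seed(29)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
  g <- factor(sample(letters[1:3], 60, replace = TRUE))
  f_ours <- crfeseg:::anova_f_stats(X, g)
  f_base <- vapply(1:8, function(j) {
    stats::oneway.test(X[, j] ~ g, var.equal = TRUE)$statistic
  }, numeric(1))
  expect_equal(unname(f_ours), unname(f_base), tolerance = 1e-10)
})

test_that("a label-copy feature dominates the ANOVA ranking", {
  set.seed(30)
  y <- rep(c(0, 1), 25)
  X <- matrix(rnorm(50 * 50), 50, 50,
              dimnames = list(NULL, paste0("f", 1:50)))
  X[, 17] <- y
  r <- rank_features(X, y, "anova_f")
  expect_equal(r$name[1], "f17")
  # permutation invariance of the ranking
  perm <- sample(50)
  r2 <- rank_features(X[perm, ], y[perm], "anova_f")
  expect_equal(r2$name, r$name)
})

test_that("all three methods recover planted informative features", {
  d <- make_planted(seed = 31)
  for (m in c("model_importance", "anova_f", "rfe")) {
    r <- rank_features(d$X, d$y, m, seed = 7)
    top10 <- r$name[1:10]
    expect_true(all(paste0("signal", 1:5) %in% top10), label = m)
  }
  ens <- ensemble_rank(d$X, d$y, seed = 7)
  expect_true(all(paste0("signal", 1:5) %in% ens$ensemble$name[1:10]))
  expect_equal(sum(ens$ensemble$score), 1, tolerance = 1e-9)
  expect_error(rank_features(d$X, rep(1, nrow(d$X)), "anova_f"), "classes")
})

test_that("the feature-count search lands on the signal plateau", {
  d <- make_planted(n = 100, p_noise = 90, n_signal = 10, effect = 1.5,
                    seed = 32)
  res <- choose_feature_count(d$X, d$y, count_grid = seq(5, 50, 5),
                              cv_folds = 5, seed = 3)
  expect_lte(res$chosen_count, 20)
  expect_equal(res$cv_score_by_count$k, seq(5, 50, 5))
  single <- choose_feature_count(d$X, d$y, count_grid = 5, seed = 3)
  expect_equal(single$chosen_count, 5)
})

test_that("the importance cutoff keeps scores above threshold, capped", {
  r <- data.frame(name = paste0("f", 1:6),
                  score = c(0.5, 0.3, 0.15, 0.04, 0.005, 0.005),
                  rank = 1:6)
  sel <- apply_cutoff(r, cutoff = 0.01, max_keep = 30)
  expect_equal(sel$chosen_count, 4L)
  expect_equal(sel$selected_names, paste0("f", 1:4))
  all_above <- data.frame(name = paste0("f", 1:40), score = rep(1 / 40, 40),
                          rank = 1:40)
  expect_equal(apply_cutoff(all_above, 0.01, 30)$chosen_count, 30L)
  expect_equal(apply_cutoff(r, cutoff = 1.0)$chosen_count, 0L)
})

test_that("correlation report clusters duplicated features first", {
  set.seed(33)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  X[, "b"] <- X[, "a"]
  rep <- correlation_cluster_report(X)
  expect_equal(rep$correlation["a", "b"], 1)
  expect_equal(sort(rep$hclust$merge[1, ]), c(-2, -1))   # a,b merge first
  expect_equal(stats::cor(X[, "c"], -X[, "c"]), -1)
  # independent features stay near zero correlation at n = 1000
  Xi <- matrix(rnorm(1000 * 6), 1000, 6,
               dimnames = list(NULL, paste0("g", 1:6)))
  ri <- correlation_cluster_report(Xi)
  off <- ri$correlation[upper.tri(ri$correlation)]
  expect_lt(max(abs(off)), 0.11)
})
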
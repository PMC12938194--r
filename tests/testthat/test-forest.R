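# Random forests: OOB bookkeeping, grouped folds, permutation importance.

# toy table with the canonical feature names, driven by one feature
toy_features <- function(n, seed, signal = "v", noise = 0) {
  set.seed(seed)
  X <- tibble::as_tibble(setNames(
    lapply(feature_cols(), function(f) rnorm(n)), feature_cols()))
  y <- as.integer(X[[signal]] + rnorm(n, 0, noise) > 0)
  list(X = X, y = y)
}

test_that("a separable single-feature rule is learned almost perfectly", {
  d <- toy_features(500, 61)
  f <- train_forest(d$X, d$y, forest_config("classification", 100, seed = 1))
  ev <- evaluate_forest(f, d$X, d$y, "oob")
  expect_gt(ev$accuracy, 0.95)
})

test_that("depth-one trees are stumps", {
  d <- toy_features(300, 62)
  f <- train_forest(d$X, d$y,
                    forest_config("classification", 20, max_depth = 1, seed = 2))
  info <- ranger::treeInfo(f$ranger, 1)
  expect_lte(sum(info$terminal), 2)
  expect_lte(max(vapply(1:20, function(i)
    sum(ranger::treeInfo(f$ranger, i)$terminal), 0)), 2)
})

test_that("a single-class target is rejected", {
  d <- toy_features(100, 63)
  expect_error(train_forest(d$X, rep(1L, 100),
                            forest_config("classification", 10)),
               "single class")
})

test_that("the bootstrap leaves about a third of rows out of bag", {
  d <- toy_features(2000, 64)
  f <- train_forest(d$X, d$y, forest_config("classification", 60, seed = 3))
  oob_frac <- mean(f$inbag == 0)
  expect_lt(abs(oob_frac - exp(-1)), 0.03)
})

test_that("grouped folds partition participants evenly and disjointly", {
  folds <- group_kfold(1:34, K = 5, seed = 4)
  sizes <- sort(as.vector(table(folds$fold)))
  expect_equal(sizes, c(6, 7, 7, 7, 7))
  expect_equal(sort(folds$participant_id), 1:34)
  expect_error(group_kfold(1:34, K = 1), "at least 2")
  expect_error(group_kfold(1:3, K = 5), "fewer participants")
})

test_that("grouped CV never lets a participant straddle train and test", {
  d <- toy_features(400, 65)
  groups <- rep(1:20, each = 20)
  folds <- group_kfold(groups, K = 5, seed = 5)
  fold_of <- folds$fold[match(groups, folds$participant_id)]
  for (k in 1:5) {
    expect_length(intersect(groups[fold_of == k], groups[fold_of != k]), 0)
  }
})

test_that("metrics match their definitions on degenerate predictors", {
  m <- driftlearn:::.forest_metrics("classification", c(1, 0, 1, 1), c(1, 0, 1, 1))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  y <- c(1, 2, 3, 4)
  m2 <- driftlearn:::.forest_metrics("regression", y, rep(mean(y), 4))
  expect_equal(m2$rmse, sqrt(mean((y - mean(y))^2)))
  expect_equal(m2$r2, 0)
  m3 <- driftlearn:::.forest_metrics("regression", y, y)
  expect_equal(m3$rmse, 0)
  expect_equal(m3$r2, 1)
})

test_that("out-of-bag and grouped-CV accuracy agree on a large table", {
  d <- toy_features(5000, 66, noise = 0.5)
  groups <- rep(1:25, each = 200)
  f <- train_forest(d$X, d$y, forest_config("classification", 100, seed = 6))
  oob <- evaluate_forest(f, d$X, d$y, "oob")
  cv <- evaluate_forest(f, d$X, d$y, "group_cv", groups = groups, K = 5,
                        seed = 7)
  expect_lt(abs(oob$accuracy - mean(cv$accuracy)), 0.05)
})

# (the 10-seed planted-signal importance harness lives in
# test-acceptance.R)
test_that("importance is normalized and ignores constant features", {
  d <- toy_features(400, 68, noise = 0.3)
  d$X$Rhat <- 1   # constant, uninformative
  f <- train_forest(d$X, d$y, forest_config("classification", 60, seed = 8))
  imp <- permutation_importance(f, d$X, d$y, repeats = 8, seed = 9)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(imp$importance >= 0))
  expect_lt(imp$importance[imp$feature == "Rhat"], 0.02)
})

test_that("top-k refits behave at the boundaries", {
  d <- toy_features(300, 69, noise = 0.3)
  cfg <- forest_config("classification", 40, seed = 10)
  f <- train_forest(d$X, d$y, cfg)
  imp <- permutation_importance(f, d$X, d$y, repeats = 5, seed = 11)
  full_vs_all <- topk_refit(d$X, d$y, imp, k = 11, config = cfg)
  # k = all features: both rows are the same model under the same seed
  expect_equal(full_vs_all$accuracy[1], full_vs_all$accuracy[2])
  expect_error(topk_refit(d$X, d$y, imp, k = 0, config = cfg), "between")
  expect_error(topk_refit(d$X, d$y, imp, k = 12, config = cfg), "between")
})

test_that("pruning noise features does not hurt a sparse signal", {
  set.seed(70)
  n <- 600
  X <- tibble::as_tibble(setNames(
    lapply(feature_cols(), function(f) rnorm(n)), feature_cols()))
  y <- as.integer(X$v + X$Z0 + X$Acc_CMA_AllPast + rnorm(n, 0, 0.4) > 0)
  cfg <- forest_config("classification", 60, seed = 12)
  f <- train_forest(X, y, cfg)
  imp <- permutation_importance(f, X, y, repeats = 8, seed = 13)
  res <- topk_refit(X, y, imp, k = 8, config = cfg)
  expect_gte(res$accuracy[res$model == "top8"],
             res$accuracy[res$model == "full"] - 0.02)
})
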
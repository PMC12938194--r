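# Random forests over the trial-level feature table: bagged Gini trees for
# accuracy classification (all features at every split), variance-reduction
# trees with mtry = one third for log-RT regression; participant-grouped
# cross-validation, out-of-bag evaluation, repeated OOB permutation
# importance and the Top-k refit comparison.  Tree growing is delegated to
# ranger; the OOB bookkeeping, grouped folds and importance procedures are
# implemented here.

#' Random-forest configuration
#'
#' @param task `"classification"` (trial accuracy, Gini splitting, all
#'   features tried at every split) or `"regression"` (log RT of correct
#'   trials, variance-reduction splitting, one third of the features).
#' @param n_trees Number of trees (default 300).
#' @param max_depth Maximum tree depth (default 10).
#' @param min_leaf Minimum terminal node size (default 5).
#' @param mtry Features tried per split; `NULL` resolves to all features
#'   (classification) or `ceiling(p/3)` (regression).
#' @param seed Integer seed.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(task = c("classification", "regression"),
                          n_trees = 300L, max_depth = 10L, min_leaf = 5L,
                          mtry = NULL, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_trees >= 1, max_depth >= 1, min_leaf >= 1)
  structure(list(task = task, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), mtry = mtry,
                 seed = as.integer(seed)),
            class = "forest_config")
}

.resolve_mtry <- function(cfg, p) {
  if (!is.null(cfg$mtry)) return(min(as.integer(cfg$mtry), p))
  if (cfg$task == "classification") p else as.integer(ceiling(p / 3))
}

# impute the first-trial RT-CMA gap from training data only
.fill_rt_cma <- function(X, value = NULL) {
  if (!"RT_CMA_AllPast" %in% names(X)) return(list(X = X, value = value))
  col <- X$RT_CMA_AllPast
  if (is.null(value)) value <- median(col, na.rm = TRUE)
  col[is.na(col)] <- value
  X$RT_CMA_AllPast <- col
  list(X = X, value = value)
}

#' Train a bagged forest on the feature table
#'
#' Grows `n_trees` CART trees on bootstrap resamples with the depth and
#' leaf-size limits of the configuration, storing per-tree in-bag counts so
#' out-of-bag indices are available to the evaluation and importance
#' procedures. Missing first-trial RT-CMA values are imputed with the
#' training-set median log RT history (stored for reuse at prediction
#' time).
#'
#' @param X Feature tibble (columns from [feature_cols()]; extra columns
#'   are ignored).
#' @param y Target: 0/1 accuracy (classification) or numeric log RT
#'   (regression).
#' @param config A [forest_config()].
#' @param features Feature columns to use (default: the canonical 11 that
#'   are present in `X`).
#' @return An object of class `dl_forest`.
#' @export
train_forest <- function(X, y, config = forest_config(),
                         features = intersect(feature_cols(), names(X))) {
  stopifnot(inherits(config, "forest_config"), length(features) >= 1)
  Xf <- X[, features, drop = FALSE]
  fill <- .fill_rt_cma(Xf)
  Xf <- fill$X
  if (anyNA(Xf)) rlang::abort("feature table contains missing values")
  if (config$task == "classification") {
    y <- factor(y, levels = sort(unique(y)))
    if (nlevels(y) < 2) rlang::abort("degenerate target: a single class")
  } else {
    y <- as.numeric(y)
  }
  rf <- ranger::ranger(
    x = as.data.frame(Xf, check.names = FALSE), y = y,
    num.trees = config$n_trees,
    mtry = .resolve_mtry(config, length(features)),
    min.node.size = config$min_leaf,
    max.depth = config$max_depth,
    replace = TRUE, keep.inbag = TRUE,
    seed = config$seed, num.threads = 1
  )
  inbag <- matrix(unlist(rf$inbag.counts), nrow = nrow(Xf))
  structure(list(ranger = rf, task = config$task, features = features,
                 config = config, rt_cma_fill = fill$value,
                 inbag = inbag, y_levels = if (is.factor(y)) levels(y)),
            class = "dl_forest")
}

#' @export
print.dl_forest <- function(x, ...) {
  cat(sprintf("Random forest (%s): %d trees, %d features, OOB error %.4f\n",
              x$task, x$config$n_trees, length(x$features),
              x$ranger$prediction.error))
  invisible(x)
}

#' Predict from a trained forest
#'
#' @param object A [train_forest()] result.
#' @param data Feature tibble.
#' @param ... Unused.
#' @return Numeric vector: class (0/1) for classification, value for
#'   regression.
#' @export
predict.dl_forest <- function(object, data, ...) {
  Xf <- .fill_rt_cma(data[, object$features, drop = FALSE],
                     object$rt_cma_fill)$X
  p <- predict(object$ranger, data = as.data.frame(Xf, check.names = FALSE),
               num.threads = 1)$predictions
  if (object$task == "classification") as.numeric(as.character(p)) else p
}

#' Out-of-bag predictions
#'
#' Aggregates per-tree predictions over the trees for which each training
#' row was out of bag (majority vote for classification, mean for
#' regression). Rows in-bag for every tree (rare) fall back to the
#' all-tree aggregate.
#'
#' @param forest A [train_forest()] result.
#' @param X The training feature tibble (possibly with one column
#'   permuted).
#' @return Numeric vector of OOB predictions.
#' @export
oob_predict <- function(forest, X) {
  Xf <- .fill_rt_cma(X[, forest$features, drop = FALSE],
                     forest$rt_cma_fill)$X
  all_pred <- predict(forest$ranger,
                      data = as.data.frame(Xf, check.names = FALSE),
                      predict.all = TRUE, num.threads = 1)$predictions
  oob <- forest$inbag == 0
  n_oob <- rowSums(oob)
  if (forest$task == "classification") {
    # per-tree class indices -> OOB vote share of the second level
    votes2 <- rowSums((all_pred == 2) * oob) / pmax(n_oob, 1)
    fallback <- rowMeans(all_pred == 2)
    votes2[n_oob == 0] <- fallback[n_oob == 0]
    lev <- as.numeric(forest$y_levels)
    ifelse(votes2 > 0.5, lev[2], lev[1])
  } else {
    out <- rowSums(all_pred * oob) / pmax(n_oob, 1)
    out[n_oob == 0] <- rowMeans(all_pred)[n_oob == 0]
    out
  }
}

# task metrics; F1 on the "correct" (1) class as positive
.forest_metrics <- function(task, y, pred) {
  if (task == "classification") {
    y <- as.numeric(as.character(y))
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(accuracy = mean(pred == y), f1 = f1)
  } else {
    rmse <- sqrt(mean((pred - y)^2))
    ssr <- sum((y - pred)^2); sst <- sum((y - mean(y))^2)
    tibble::tibble(rmse = rmse, r2 = 1 - ssr / max(sst, 1e-300))
  }
}

#' Participant-grouped K-fold assignments
#'
#' Partitions participants (never trials) into K folds whose sizes differ
#' by at most one participant, so no participant's trials ever straddle a
#' train/test split.
#'
#' @param groups Vector of participant ids (one per row, or the unique
#'   ids).
#' @param K Number of folds (default 5; must be >= 2 and <= number of
#'   distinct participants).
#' @param seed Optional integer seed for the shuffle.
#' @return A tibble `participant_id`, `fold`.
#' @export
group_kfold <- function(groups, K = 5L, seed = NULL) {
  ids <- unique(groups)
  if (K < 2) rlang::abort("K must be at least 2")
  if (length(ids) < K) rlang::abort("fewer participants than folds")
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(ids)
  tibble::tibble(
    participant_id = shuffled,
    fold = rep_len(seq_len(K), length(ids))
  ) |> dplyr::arrange(.data$participant_id)
}

#' Evaluate a forest out-of-bag or by participant-grouped K-fold CV
#'
#' `"oob"` aggregates the training rows' out-of-bag predictions.
#' `"group_cv"` refits the forest configuration on each training fold
#' (re-imputing the RT-CMA gap from that fold only) and scores the held-out
#' participants.
#'
#' @param forest A [train_forest()] result (supplies the configuration for
#'   CV refits).
#' @param X,y Feature table and target.
#' @param scheme `"oob"` or `"group_cv"`.
#' @param groups Participant id per row (required for `"group_cv"`).
#' @param K Number of folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @return A tibble of metrics: one row for `"oob"`, one row per fold for
#'   `"group_cv"` (summarise across folds as needed).
#' @export
evaluate_forest <- function(forest, X, y, scheme = c("oob", "group_cv"),
                            groups = NULL, K = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "oob") {
    pred <- oob_predict(forest, X)
    return(.forest_metrics(forest$task, y, pred) |>
             dplyr::mutate(scheme = "oob", .before = 1))
  }
  if (is.null(groups)) rlang::abort("group_cv needs `groups`")
  folds <- group_kfold(groups, K, seed)
  fold_of <- folds$fold[match(groups, folds$participant_id)]
  out <- lapply(seq_len(K), function(k) {
    tr <- fold_of != k
    fit_k <- train_forest(X[tr, ], y[tr], forest$config,
                          features = forest$features)
    pred <- predict(fit_k, X[!tr, ])
    .forest_metrics(forest$task, y[!tr], pred) |>
      dplyr::mutate(scheme = "group_cv", fold = k, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Permutation importance on out-of-bag samples
#'
#' For each feature and repeat, the feature's values are permuted and the
#' out-of-bag performance drop recorded (accuracy drop for classification,
#' RMSE increase for regression). Drops are averaged over `repeats`,
#' floored at zero and normalized to sum to one.
#'
#' @param forest A [train_forest()] result.
#' @param X,y Training feature table and target.
#' @param repeats Permutations per feature (default 50).
#' @param seed Integer seed.
#' @return A tibble of class `dl_importance`: `feature`, `mean_drop`,
#'   `importance` (normalized), `rank`.
#' @export
permutation_importance <- function(forest, X, y, repeats = 50L, seed = 1L) {
  set.seed(seed)
  base <- .forest_metrics(forest$task, y, oob_predict(forest, X))
  base_val <- if (forest$task == "classification") base$accuracy else base$rmse
  n <- nrow(X)
  drops <- vapply(forest$features, function(f) {
    mean(vapply(seq_len(repeats), function(r) {
      Xp <- X
      Xp[[f]] <- X[[f]][sample.int(n)]
      m <- .forest_metrics(forest$task, y, oob_predict(forest, Xp))
      if (forest$task == "classification") base_val - m$accuracy
      else m$rmse - base_val
    }, 0))
  }, 0)
  pos <- pmax(drops, 0)
  total <- sum(pos)
  out <- tibble::tibble(
    feature = forest$features,
    mean_drop = unname(drops),
    importance = if (total > 0) unname(pos) / total else rep(0, length(pos))
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("dl_importance", class(out))
  out
}

#' Compare the full-feature model with a Top-k refit
#'
#' Refits the forest on the `k` most important features and reports both
#' models' out-of-bag (and optionally grouped-CV) metrics side by side.
#'
#' @param X,y Feature table and target.
#' @param importance A [permutation_importance()] result.
#' @param k Number of top features to keep (default 8).
#' @param config A [forest_config()].
#' @param groups Optional participant ids to add grouped-CV metrics.
#' @param K,seed CV parameters.
#' @return A tibble with one metric row per (model, scheme).
#' @export
topk_refit <- function(X, y, importance, k = 8L, config = forest_config(),
                       groups = NULL, K = 5L, seed = 1L) {
  feats_all <- importance$feature
  if (k < 1 || k > length(feats_all)) {
    rlang::abort("`k` must be between 1 and the number of features")
  }
  top <- importance$feature[order(importance$rank)][seq_len(k)]
  eval_one <- function(features, label) {
    f <- train_forest(X, y, config, features = features)
    res <- evaluate_forest(f, X, y, "oob") |> dplyr::mutate(model = label)
    if (!is.null(groups)) {
      cv <- evaluate_forest(f, X, y, "group_cv", groups, K, seed) |>
        dplyr::mutate(model = label)
      res <- dplyr::bind_rows(res, cv)
    }
    res
  }
  dplyr::bind_rows(
    eval_one(feats_all, "full"),
    eval_one(top, paste0("top", k))
  ) |> dplyr::select("model", dplyr::everything())
}
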
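# Preprocessing and the repeated-measures ANOVA stage.

test_that("participant screening reproduces the exclusion structure", {
  fx <- make_exclusion_fixture(seed = 11)
  tr <- generate_design(40, 1, seed = 12) |>
    dplyr::mutate(rt = 1 + trial_index / 100, accuracy = 1L)
  cl <- preprocess_trials(tr, fx)
  expect_equal(length(unique(cl$trials$participant_id)), 34)
  expect_equal(sum(cl$exclusion_log$reason == "learning_accuracy"), 5)
  expect_equal(sum(cl$exclusion_log$reason == "protocol"), 1)
})

test_that("a clean fixture retains everyone with empty logs", {
  fx <- make_exclusion_fixture(seed = 13, n_low_acc = 0, n_protocol = 0)
  tr <- generate_design(40, 1, seed = 14) |>
    dplyr::mutate(rt = 1 + trial_index / 100, accuracy = 1L)
  cl <- preprocess_trials(tr, fx)
  expect_equal(length(unique(cl$trials$participant_id)), 40)
  expect_true(all(cl$exclusion_log$reason == "none"))
  expect_equal(nrow(cl$outlier_log), 0)
})

test_that("the RT floor removes exactly the sub-floor trial", {
  tr <- generate_design(1, 6, seed = 15) |>
    dplyr::mutate(rt = 1 + trial_index / 50, accuracy = 1L)
  tr$rt[7] <- 0.05                       # one 50 ms trial
  cl <- preprocess_trials(tr)
  expect_equal(nrow(cl$outlier_log), 1)
  expect_equal(cl$outlier_log$trial_index, 7)
  expect_equal(cl$outlier_log$bound, "low")
  expect_equal(nrow(cl$trials), nrow(tr) - 1)
})

test_that("a constant dependent variable yields null F statistics", {
  vals <- matrix(0.7, 5, 15)
  out <- rm_anova(cellmean_trials(vals), "accuracy")
  expect_equal(out$statistic, rep(0, 3))
  expect_equal(out$p_value, rep(1, 3))
  expect_equal(out$pes, rep(0, 3))
})

test_that("ANOVA sums of squares match the brute-force oracle", {
  set.seed(16)
  n <- 4
  vals <- matrix(rnorm(n * 15, 0.8, 0.1), n, 15)
  out <- rm_anova(cellmean_trials(vals), "accuracy")
  oracle <- oracle_rm_ss(vals)
  for (i in seq_along(c("hierarchy", "block", "interaction"))) {
    o <- oracle[[i]]
    expect_equal(out$ss[i], unname(o["ss"]), tolerance = 1e-9)
    expect_equal(out$ss_error[i], unname(o["ss_error"]), tolerance = 1e-9)
    expect_equal(out$statistic[i], unname(o["F"]), tolerance = 1e-9)
  }
  # effect + error within-subject SS are internally consistent
  tot <- sum(out$ss) + sum(out$ss_error)
  arr <- array(t(vals), dim = c(5, 3, n))
  m_s <- apply(arr, 3, mean)
  within_tot <- sum(sweep(vals, 1, m_s)^2)
  expect_equal(tot, within_tot, tolerance = 1e-9 * within_tot)
})

test_that("GG epsilon lies in its admissible band and shrinks both dfs", {
  set.seed(17)
  vals <- matrix(rnorm(12 * 15, 0.7, 0.05), 12, 15)
  out <- rm_anova(cellmean_trials(vals), "accuracy")
  expect_true(all(out$gg_epsilon > 1 / out$df1 & out$gg_epsilon <= 1 + 1e-9))
  expect_equal(out$df1_gg / out$df1, out$df2_gg / out$df2, tolerance = 1e-12)
})

test_that("a planted hierarchy effect is detected across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    base <- rep(c(0.9, 0.8, 0.7), each = 5)
    vals <- t(replicate(20, base + rnorm(15, 0, 0.02)))
    out <- rm_anova(cellmean_trials(vals), "accuracy")
    hits <- hits + (out$p_value[out$effect == "hierarchy"] < 0.001)
  }
  expect_gte(hits, 9)
})

test_that("pairwise comparisons detect planted orderings and nothing else", {
  set.seed(18)
  base <- rep(c(0.9, 0.8, 0.7), each = 5)
  vals <- t(replicate(15, base + rnorm(15, 0, 0.01)))
  pw <- pairwise_comparisons(cellmean_trials(vals), "accuracy", "hierarchy")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj < 0.001))
  # identical level means: nothing significant
  flat <- t(replicate(15, rep(0.8, 15) + rnorm(15, 0, 0.01)))
  pw0 <- pairwise_comparisons(cellmean_trials(flat), "accuracy", "hierarchy")
  expect_true(all(pw0$p_adj > 0.05))
  # antisymmetry: the estimate flips sign when levels swap
  expect_equal(
    pw$estimate[pw$level_a == 1 & pw$level_b == 2],
    -(mean(vals[, 6:10]) - mean(vals[, 1:5])),
    tolerance = 1e-9)
})

test_that("missing participant cells error by default and can be omitted", {
  tr <- small_trials() |>
    dplyr::filter(!(participant_id == 1 & rule_hierarchy == 3 & block == 5 &
                      accuracy == 1))
  expect_error(rm_anova(tr, "rt"), "missing")
  expect_warning(out <- rm_anova(tr, "rt", na_action = "omit"), "dropping")
  expect_equal(nrow(out), 3)
})
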
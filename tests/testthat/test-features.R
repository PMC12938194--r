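# The trial-level feature table and its anti-leakage guarantees.

test_that("the feature table has exactly the eleven canonical columns", {
  fe <- build_features(small_trials(), quick_fit())
  expect_true(all(feature_cols() %in% names(fe)))
  expect_false("z" %in% names(fe))          # collinearity exclusion
  expect_true("Z0" %in% names(fe))
  expect_equal(length(feature_cols()), 11)
  # Z0 is the product of the start proportion and the boundary
  pars <- quick_fit()$subject_means |>
    tidyr::pivot_wider(names_from = parameter, values_from = estimate)
  expect_equal(sort(unique(round(fe$Z0, 9))),
               sort(unique(round(pars$z * pars$a, 9))))
})

test_that("history features equal the hand-computed running means", {
  tr <- small_trials() |> dplyr::filter(participant_id == 1)
  tr$accuracy[1:3] <- c(1L, 0L, 1L)
  fe <- build_features(tr, quick_fit())
  expect_equal(fe$Acc_CMA_AllPast[1:3], c(0.5, 1, 0.5))
  expect_true(is.na(fe$RT_CMA_AllPast[1]))
  expect_equal(fe$RT_CMA_AllPast[2], log(tr$rt[1]))
  expect_equal(fe$RT_CMA_AllPast[3], mean(log(tr$rt[1:2])))
})

test_that("history features never see the present or the future", {
  tr <- small_trials()
  fe <- build_features(tr, quick_fit())
  set.seed(51)
  for (rep_i in 1:5) {
    cut <- sample(10:80, 1)
    mod <- tr |>
      dplyr::mutate(
        rt = ifelse(trial_index >= cut, rt + runif(dplyr::n(), 0.5, 2), rt),
        accuracy = ifelse(trial_index >= cut,
                          1L - accuracy, accuracy))
    fe2 <- build_features(mod, quick_fit())
    before <- fe$trial_index <= cut   # CMA at cut uses trials < cut only
    expect_equal(fe$Acc_CMA_AllPast[before], fe2$Acc_CMA_AllPast[before])
    expect_equal(fe$RT_CMA_AllPast[before], fe2$RT_CMA_AllPast[before])
  }
})

test_that("feature CSV keeps non-syntactic canonical names", {
  fe <- build_features(small_trials(), quick_fit())
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fe, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_true('"Block_ID*Rule_Hierarchy"' %in% header ||
                "Block_ID*Rule_Hierarchy" %in% header)
})
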
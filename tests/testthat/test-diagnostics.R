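# R-hat, HDIs and posterior predictive checks.

test_that("R-hat is near one for chains sampling the same distribution", {
  set.seed(1)
  d <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(gelman_rubin(d)$rhat - 1), 0.05)
})

test_that("R-hat flags separated chains", {
  set.seed(2)
  d <- cbind(rnorm(500, 0, 1), rnorm(500, 10, 1))
  expect_gt(gelman_rubin(d)$rhat, 1.1)
})

test_that("R-hat equals the between/within formula evaluated directly", {
  set.seed(3)
  d <- matrix(rnorm(20), 10, 2)
  W <- mean(apply(d, 2, var))
  B <- 10 * var(colMeans(d))
  manual <- sqrt(((10 - 1) / 10 * W + B / 10) / W)
  expect_equal(gelman_rubin(d)$rhat, manual, tolerance = 1e-12)
})

test_that("R-hat rejects degenerate inputs", {
  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(10), 5, 2)), "10 retained")
})

test_that("the HDI of a constant sample is degenerate", {
  expect_equal(hdi(rep(3.2, 25)), c(3.2, 3.2))
})

test_that("the 95% HDI of a standard normal approaches +/-1.96", {
  set.seed(4)
  h <- hdi(rnorm(1e5))
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
})

test_that("the 95% HDI of a uniform sample has length about 0.95", {
  set.seed(5)
  h <- hdi(runif(1e5))
  expect_lt(abs(diff(h) - 0.95), 0.01)
})

test_that("HDI input validation works", {
  expect_error(hdi(numeric(0)), "empty")
  expect_error(hdi(rnorm(50), mass = 1.2), "mass")
})

test_that("HDI non-overlap is symmetric, strict, and endpoint-inclusive", {
  set.seed(6)
  a <- rnorm(500, 0, 0.1); b <- rnorm(500, 10, 0.1)
  expect_true(hdi_significant(a, b))
  expect_true(hdi_significant(b, a))
  expect_false(hdi_significant(a, a))
  # shared endpoint counts as overlap
  x <- rep(c(0, 1), 50); y <- rep(c(1, 2), 50)
  expect_equal(hdi(x), c(0, 1))
  expect_false(hdi_significant(x, y))
})

med_rt_gap <- function(ppc, relative = FALSE) {
  med <- ppc$cells |>
    dplyr::select(rule_hierarchy, block, source, `50%`) |>
    tidyr::pivot_wider(names_from = source, values_from = `50%`)
  gap <- abs(med$observed - med$simulated)
  if (relative) gap <- gap / med$observed
  median(gap)
}

test_that("a self-consistent fit passes its posterior predictive check", {
  fit <- quick_fit()
  ppc <- posterior_predictive_check(fit, seed = 99)
  expect_s3_class(ppc, "ddm_ppc")
  # typical (median) cell medians agree to ~10%; extreme quantiles of slow
  # cells are noisy at this sample size and are not asserted here
  expect_lt(med_rt_gap(ppc, relative = TRUE), 0.10)
  expect_lt(ppc$accuracy_discrepancy, 0.25)
})

test_that("a planted non-decision misfit is detected by the PPC", {
  fit <- quick_fit()
  wrong <- fit
  wrong$subject_means <- wrong$subject_means |>
    dplyr::mutate(estimate = ifelse(parameter == "t0", estimate + 0.5,
                                    estimate))
  ppc <- posterior_predictive_check(wrong, seed = 100)
  expect_gte(med_rt_gap(ppc), 0.4)
})

test_that("the PPC skips and warns about uncovered participants", {
  fit <- quick_fit()
  alien <- small_trials() |> dplyr::mutate(participant_id = participant_id + 100)
  expect_warning(posterior_predictive_check(fit, alien, seed = 1), "skipped")
})
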
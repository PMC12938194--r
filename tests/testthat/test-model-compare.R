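# Model space, information criteria and PSIS-LOO comparison machinery.

fake_fit <- function(pointwise, model_id = 1, loglik_hat = sum(colMeans(pointwise)),
                     max_rhat = 1.0, rt = seq_len(ncol(pointwise))) {
  structure(list(
    spec = model_spec(model_id), loglik_hat = loglik_hat,
    n_trials = ncol(pointwise), max_rhat = max_rhat,
    pointwise = pointwise, trials = tibble::tibble(rt = rt)
  ), class = "ddm_fit")
}

test_that("free-parameter counts follow the factor maps", {
  expect_identical(count_free_params(1), 12L)
  expect_identical(count_free_params(2), 20L)
  expect_identical(count_free_params(3), 28L)
  expect_identical(count_free_params(4), 60L)
  s <- model_spec(4)
  expect_identical(count_free_params(s), count_free_params(s)) # pure
  expect_error(model_spec(5), "1, 2, 3 or 4")
})

test_that("information criteria follow their defining formulas", {
  f <- fake_fit(matrix(-1, 200, 10), loglik_hat = -10)
  expect_equal(ddm_aic(f, k = 0), 20)
  expect_equal(ddm_aic(f, k = 7) - ddm_aic(f, k = 3), 2 * (7 - 3))
  expect_equal(ddm_bic(f, k = 2, n_trials = 100), 2 * log(100) + 20)
  expect_error(ddm_bic(f, k = 2, n_trials = 0), "positive")
})

test_that("a constant predictive density gives elpd = n log p exactly", {
  p <- 0.2
  ll <- matrix(log(p), 150, 12)
  res <- elpd_loo(ll)
  expect_equal(res$elpd, 12 * log(p), tolerance = 1e-10)
  expect_equal(res$se, 0)
})

test_that("LOO never beats the in-sample log predictive density", {
  set.seed(7)
  for (i in 1:10) {
    ll <- matrix(rnorm(150 * 20, mean = -1, sd = 0.3), 150, 20)
    res <- suppressWarnings(elpd_loo(ll))
    lpd <- sum(apply(ll, 2, function(x) {
      m <- max(x); m + log(mean(exp(x - m)))
    }))
    expect_lte(res$elpd, lpd + 1e-8)
  }
})

test_that("LOO requires a reasonable number of draws", {
  expect_error(elpd_loo(matrix(-1, 50, 5)), "100")
})

test_that("identical fits compare as exactly equivalent", {
  set.seed(8)
  ll <- matrix(rnorm(200 * 15, -1, 0.2), 200, 15)
  f1 <- fake_fit(ll, 1); f2 <- fake_fit(ll, 2)
  cmp <- compare_models(list(f1, f2))
  expect_equal(cmp$pairwise$delta_elpd, 0)
  expect_equal(cmp$pairwise$se_delta, 0)
  expect_false(cmp$pairwise$significant)
})

test_that("pairwise standard errors come from pointwise differences", {
  set.seed(9)
  ll1 <- matrix(rnorm(200 * 30, -1.0, 0.2), 200, 30)
  ll2 <- matrix(rnorm(200 * 30, -1.2, 0.2), 200, 30)
  f1 <- fake_fit(ll1, 1); f2 <- fake_fit(ll2, 2)
  l1 <- suppressWarnings(elpd_loo(ll1)); l2 <- suppressWarnings(elpd_loo(ll2))
  cmp <- suppressWarnings(compare_models(list(f1, f2)))
  d <- l1$pointwise - l2$pointwise
  expect_equal(cmp$pairwise$delta_elpd, sum(d), tolerance = 1e-10)
  expect_equal(cmp$pairwise$se_delta, sd(d) * sqrt(30), tolerance = 1e-10)
})

test_that("fits on different trial sets cannot be compared", {
  ll <- matrix(-1, 150, 10)
  f1 <- fake_fit(ll, 1)
  f2 <- fake_fit(ll, 2, rt = seq_len(10) + 0.5)
  expect_error(compare_models(list(f1, f2)), "identical trial sets")
  f3 <- fake_fit(matrix(-1, 150, 9), 2)
  expect_error(compare_models(list(f1, f3)), "identical trial sets")
})

test_that("selection prefers the lowest AIC among converged fits", {
  ll <- matrix(-1, 150, 10)
  good <- fake_fit(ll, 1, loglik_hat = -40, max_rhat = 1.01)
  better_unconverged <- fake_fit(ll, 4, loglik_hat = 10, max_rhat = 1.4)
  cmp <- compare_models(list(good, better_unconverged))
  expect_equal(cmp$selected, 1)
})
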
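# Wiener first-passage-time density and log-likelihood.

test_that("density agrees with a long fixed-truncation reference series", {
  sets <- list(c(v = 0.92, a = 2.98, t0 = 0.73, z = 0.29),
               c(v = 0.38, a = 6.36, t0 = 0.95, z = 0.23),
               c(v = -0.8, a = 1.5, t0 = 0.2, z = 0.6))
  for (p in sets) {
    tg <- seq(p["t0"] + 0.01, p["t0"] + 6, by = 0.035)
    for (b in c("upper", "lower")) {
      f <- wfpt_density(tg, p["v"], p["a"], p["t0"], p["z"], b)
      ref <- ref_wfpt(tg, p["v"], p["a"], p["t0"], p["z"], b)
      sel <- ref > 1e-12
      # relative agreement everywhere, which also rules out any jump at
      # the small/large-time representation switch
      expect_lt(max(abs(f[sel] - ref[sel]) / ref[sel]), 1e-6)
    }
  }
})

test_that("a drift-free symmetric process has equal boundary densities", {
  tg <- seq(0.05, 4, by = 0.05)
  up <- wfpt_density(tg, 0, 2, 0, 0.5, "upper")
  lo <- wfpt_density(tg, 0, 2, 0, 0.5, "lower")
  expect_equal(up, lo, tolerance = 1e-12)
})

test_that("the upper-boundary density integrates to the absorption probability", {
  sets <- list(c(0.92, 2.98, 0.29), c(0.60, 5.17, 0.18),
               c(-0.5, 2.0, 0.40), c(1.2, 1.5, 0.70))
  for (p in sets) {
    f <- function(t) wfpt_density(t, p[1], p[2], 0, p[3], "upper")
    I <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(I - absorption_prob(p[1], p[2], p[3])), 1e-4)
  }
})

test_that("upper and lower densities jointly integrate to one", {
  set.seed(21)
  for (i in 1:10) {
    v <- runif(1, -2, 2); a <- runif(1, 0.5, 6); z <- runif(1, 0.1, 0.9)
    Iu <- stats::integrate(function(t) wfpt_density(t, v, a, 0, z, "upper"),
                           0, Inf, rel.tol = 1e-8)$value
    Il <- stats::integrate(function(t) wfpt_density(t, v, a, 0, z, "lower"),
                           0, Inf, rel.tol = 1e-8)$value
    expect_lt(abs(Iu + Il - 1), 1e-3)
  }
})

# (the density-vs-simulation histogram check lives in test-acceptance.R)
test_that("times at or below the non-decision time carry zero density", {
  expect_equal(wfpt_density(c(0.1, 0.3), 1, 2, 0.3, 0.5), c(0, 0))
  expect_error(wfpt_density(1, NA, 2, 0.3, 0.5), "invalid")
})

test_that("the trial log-likelihood is additive and floors impossible trials", {
  tr <- tibble::tibble(rt = c(0.9, 1.4, 2.0), accuracy = c(1L, 0L, 1L))
  ll1 <- ddm_loglik(tr, 0.8, 2.5, 0.4, 0.4)
  ll2 <- ddm_loglik(dplyr::bind_rows(tr, tr), 0.8, 2.5, 0.4, 0.4)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-12)
  expect_equal(ddm_loglik(tr[0, ], 0.8, 2.5, 0.4, 0.4), 0)
  # single trial equals the log density at that point
  one <- tr[1, ]
  expect_equal(ddm_loglik(one, 0.8, 2.5, 0.4, 0.4),
               log(wfpt_density(one$rt, 0.8, 2.5, 0.4, 0.4, "upper")))
  # rt <= t0 is penalized, not -Inf
  bad <- tibble::tibble(rt = 0.2, accuracy = 1L)
  expect_equal(ddm_loglik(bad, 0.8, 2.5, 0.4, 0.4), -700)
})

test_that("the log-likelihood peaks near the generating drift", {
  set.seed(41)
  v0 <- 0.9; a0 <- 2.5; t00 <- 0.35; z0 <- 0.45
  sim <- driftlearn:::simulate_fpt_cpp(5000, v0, a0, z0, 1e-3, 60)
  tr <- tibble::tibble(rt = t00 + sim$t_dec, accuracy = sim$upper)
  grid <- seq(v0 - 0.3, v0 + 0.3, by = 0.02)
  ll <- vapply(grid, function(v) ddm_loglik(tr, v, a0, t00, z0), 0)
  expect_lt(abs(grid[which.max(ll)] - v0), 0.05)
})
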
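# The hierarchical sampler: determinism, constraints, bookkeeping.

test_that("identical seeds reproduce a fit exactly", {
  tr <- small_trials()
  cfg <- mcmc_config(2, 120, 60, adapt_window = 40, seed = 77)
  f1 <- suppressWarnings(fit_ddm(tr, 1, cfg))
  f2 <- suppressWarnings(fit_ddm(tr, 1, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$pointwise, f2$pointwise)
})

test_that("all retained draws respect the constraint region", {
  fit <- quick_fit()
  nms <- dimnames(fit$draws)[[3]]
  a_draws <- fit$draws[, , grepl("^a\\[", nms), drop = FALSE]
  z_draws <- fit$draws[, , grepl("^z\\[", nms), drop = FALSE]
  t0_draws <- fit$draws[, , grepl("^t0\\[", nms), drop = FALSE]
  sd_draws <- fit$draws[, , grepl("^sd_", nms), drop = FALSE]
  expect_true(all(a_draws > 0.1))
  expect_true(all(z_draws > 0 & z_draws < 1))
  expect_true(all(t0_draws > 0))
  expect_true(all(sd_draws > 0))
  # subject-level non-decision times sit below their cell's fastest RT
  mins <- fit$trials |>
    dplyr::group_by(participant_id, rule_hierarchy) |>
    dplyr::summarise(min_rt = min(rt), .groups = "drop")
  t0s <- fit$subject_means |>
    dplyr::filter(parameter == "t0") |>
    dplyr::left_join(mins, by = c("participant_id", "rule_hierarchy"))
  expect_true(all(t0s$estimate < t0s$min_rt))
})

test_that("acceptance history is windowed and phase-labelled", {
  fit <- quick_fit()
  acc <- fit$acceptance
  expect_true(all(acc$window_end %% fit$config$adapt_window == 0))
  expect_true(all(acc$phase %in% c("burnin", "sampling")))
  expect_true(any(acc$phase == "sampling"))
  expect_true(all(acc$rate > 0 & acc$rate < 1))
  # the pointwise matrix covers every retained draw and trial
  expect_equal(dim(fit$pointwise),
               c((fit$config$n_iter - fit$config$burn_in) * fit$config$n_chains,
                 fit$n_trials))
})

test_that("degenerate and misconfigured data are rejected", {
  tr <- small_trials()
  flat <- tr |> dplyr::mutate(rt = 1)
  expect_error(fit_ddm(flat, 1), "degenerate")
  holey <- tr |> dplyr::filter(!(participant_id == 1 & rule_hierarchy == 2))
  expect_error(fit_ddm(holey, 1), "configuration error")
  expect_error(fit_ddm(tr[0, ], 1), "empty")
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("tidy and glance summarize a fit coherently", {
  fit <- quick_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat")
                  %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(nrow(td), 12 + 12)  # hierarchy means + pooled sds
  gl <- glance(fit)
  expect_equal(gl$k, 12L)
  expect_equal(gl$AIC, 2 * 12 - 2 * fit$loglik_hat)
  expect_equal(gl$n_trials, nrow(small_trials()))
})

test_that("posterior draws and summaries persist to CSV and JSON", {
  fit <- quick_fit()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fit_draws(fit, csv)
  long <- read.csv(csv)
  expect_identical(names(long), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(long),
               prod(dim(fit$draws)[1:2]) * dim(fit$draws)[3])
  one <- subset(long, chain == 2 & parameter == "v[h1]")
  expect_equal(one$value, as.vector(fit$draws[, 2, "v[h1]"]))
  js <- withr::local_tempfile(fileext = ".json")
  write_fit_summary(fit, js)
  smry <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(smry$model_id, 1)
  expect_equal(smry$max_rhat, fit$max_rhat, tolerance = 1e-12)
  expect_equal(nrow(smry$parameters), nrow(tidy(fit)))
})

test_that("the interaction contrast averages difference-of-differences", {
  # hand-built cell-wise draws: v[h,b] = h * b exactly, so every adjacent
  # difference-of-differences equals 1
  labs <- as.vector(outer(1:3, 1:5, function(h, b) paste0("v[h", h, "b", b, "]")))
  vals <- as.vector(outer(1:3, 1:5, `*`))
  draws <- array(rep(vals, each = 40), dim = c(20, 2, 15),
                 dimnames = list(NULL, NULL, labs))
  fake <- structure(list(spec = model_spec(4), draws = draws),
                    class = "ddm_fit")
  out <- interaction_contrast(fake, "v")
  expect_equal(out$estimate, 1, tolerance = 1e-12)
  expect_equal(out$conf.low, 1, tolerance = 1e-12)
  # a hierarchy-only fit has no interaction to summarize
  expect_error(interaction_contrast(quick_fit()), "cell-wise")
})
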
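# Synthetic task designs, parameter populations and the forward simulator.

test_that("default design yields the study's trial counts", {
  des <- generate_design(34, 6, seed = 1)
  per_p <- des |> dplyr::count(participant_id)
  expect_true(all(per_p$n == 90))
  per_block <- des |> dplyr::count(participant_id, block)
  expect_true(all(per_block$n == 18))
  per_cell <- des |> dplyr::count(participant_id, block, rule_hierarchy)
  expect_true(all(per_cell$n == 6))
  # chronological index and first-trial switch convention
  firsts <- des |> dplyr::group_by(participant_id) |>
    dplyr::summarise(inc = all(diff(trial_index) == 1),
                     first_switch = rule_switch[1])
  expect_true(all(firsts$inc))
  expect_true(all(firsts$first_switch == 0))
})

test_that("minimal design has one trial per cell", {
  des <- generate_design(1, 1, seed = 2)
  expect_equal(nrow(des), 15)
  expect_equal(nrow(dplyr::distinct(des, block, rule_hierarchy)), 15)
})

test_that("invalid design sizes are rejected", {
  expect_error(generate_design(0, 6), "positive")
  expect_error(generate_design(3, 0), "positive")
  expect_error(generate_design(2.5, 6), "positive")
})

test_that("rule switch flags equal a direct rescan of the sequence", {
  des <- generate_design(2, 2, seed = 7)
  rescans <- des |> dplyr::group_by(participant_id) |>
    dplyr::mutate(expected = as.integer(
      c(0L, diff(rule_hierarchy) != 0)
    )) |> dplyr::ungroup()
  expect_identical(rescans$rule_switch, rescans$expected)
})

test_that("identical seeds give identical trial tables", {
  d1 <- generate_design(4, 3, seed = 11)
  d2 <- generate_design(4, 3, seed = 11)
  expect_identical(d1, d2)
  pop <- ddm_population("hierarchy")
  p1 <- draw_subject_params(pop, 4, seed = 12)
  t1 <- simulate_trials(d1, p1, seed = 13)
  t2 <- simulate_trials(d2, draw_subject_params(pop, 4, seed = 12), seed = 13)
  expect_identical(t1, t2)
})

test_that("zero population sds make subject values equal the group means", {
  pop <- ddm_population("hierarchy", sds = c(v = 0, a = 0, t0 = 0, z = 0))
  par <- draw_subject_params(pop, 5, seed = 1)
  joined <- dplyr::left_join(par, pop,
                             by = c("parameter", "rule_hierarchy", "block"))
  expect_equal(joined$value, joined$mean)
})

test_that("subject draws concentrate around the generating means", {
  pop <- ddm_population("hierarchy",
                        sds = c(v = 0.1, a = 0.1, t0 = 0.1, z = 0.1))
  par <- draw_subject_params(pop, 34, seed = 99)
  vh1 <- par$value[par$parameter == "v" & par$rule_hierarchy == 1]
  # within 3 standard errors of the mean of a (mildly truncated) normal
  expect_lt(abs(mean(vh1) - 0.92), 3 * 0.1 / sqrt(34))
})

test_that("inadmissible population means are rejected", {
  pop <- ddm_population("hierarchy")
  pop$mean[pop$parameter == "a"][1] <- 0.05   # violates a > 0.1
  expect_error(draw_subject_params(pop, 3, seed = 1), "admissible")
})

# (the 10-set simulator-vs-closed-form absorption sweep lives in
# test-acceptance.R; here only the symmetric special case)
test_that("a symmetric diffusion chooses both boundaries equally often", {
  set.seed(5)
  sim <- driftlearn:::simulate_fpt_cpp(20000, 0, 2, 0.5, 0.002, 60)
  expect_lt(abs(mean(sim$upper) - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("reaction times exceed the non-decision time", {
  tr <- small_trials()
  par <- draw_subject_params(ddm_population("hierarchy"), 6, seed = 302)
  t0_min <- min(par$value[par$parameter == "t0"])
  expect_true(all(tr$rt > t0_min))
  expect_true(all(tr$accuracy %in% 0:1))
})

test_that("mean decision time rises with caution and falls with drift", {
  set.seed(8)
  mt <- matrix(NA_real_, 3, 3)
  as_ <- c(1.5, 2.5, 3.5); vs <- c(0.4, 0.9, 1.6)
  for (i in 1:3) for (j in 1:3) {
    sim <- driftlearn:::simulate_fpt_cpp(3000, vs[j], as_[i], 0.5, 0.002, 60)
    mt[i, j] <- mean(sim$t_dec)
  }
  expect_true(all(diff(mt[, 1]) > 0) && all(diff(mt[, 2]) > 0) &&
                all(diff(mt[, 3]) > 0))      # increasing in a
  expect_true(all(apply(mt, 1, diff) < 0))   # decreasing in |v|
})

test_that("the screening fixture reproduces the reported composition", {
  fx <- make_exclusion_fixture(seed = 123)
  expect_equal(nrow(fx), 40)
  low <- fx$learning_accuracy < 0.8
  proto <- fx$hierarchical_response_ok == 0
  expect_equal(sum(low), 5)
  expect_equal(sum(proto), 1)
  expect_equal(sum(low & proto), 0)          # disjoint failure modes
  expect_equal(sum(low | proto) / nrow(fx), 0.15)
})

test_that("trial CSV round-trips with the canonical header", {
  tr <- small_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  header <- readLines(path, n = 1)
  expect_identical(
    header,
    "participant_id,block,rule_hierarchy,trial_index,rule_switch,rt,accuracy")
  back <- read_trial_csv(path)
  expect_equal(back$rt, tr$rt, tolerance = 1e-6)
  expect_identical(back$accuracy, tr$accuracy)
})
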
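# Planted-truth harnesses shared by the recovery and model-selection
# acceptance checks.

# generating population for the parameter-recovery run: hierarchy-level
# posterior means of the reference fit, default between-subject spread
recovery_population <- function() {
  ddm_population("hierarchy")
}

# cell-level population with a genuine hierarchy x block interaction in
# drift (the gap between adjacent hierarchies grows by 0.1 per block);
# caution, bias and non-decision time held at task-typical values
interaction_population <- function() {
  g <- tidyr::crossing(rule_hierarchy = 1:3, block = 1:5)
  dplyr::bind_rows(lapply(c("v", "a", "t0", "z"), function(p) {
    gg <- g
    gg$parameter <- p
    gg$mean <- switch(p,
      v = 1.0 - (gg$rule_hierarchy - 1) * 0.1 * gg$block,
      a = 5, t0 = 0.9, z = 0.3)
    gg$sd <- c(v = 0.1, a = 0.2, t0 = 0.05, z = 0.03)[p]
    gg
  }))
}

# simulate one planted dataset and compare all four model structures;
# `iters` may be a length-4 vector so the structures actually competing
# for selection get the longer (less noisy) chains
selection_round <- function(seed, population, n, tpc, iters, n_chains = 2) {
  iters <- rep_len(iters, 4)
  des <- generate_design(n, tpc, seed = seed * 11)
  par <- draw_subject_params(population, n, seed = seed * 13)
  tr <- simulate_trials(des, par, seed = seed * 17)
  fits <- lapply(1:4, function(m) suppressWarnings(
    fit_ddm(tr, m, mcmc_config(n_chains, iters[m], iters[m] %/% 2,
                               seed = seed * 19 + m))
  ))
  suppressWarnings(compare_models(fits))
}

# the scaled-down recovery fit shared by several acceptance checks:
# 10 subjects x 30 trials per hierarchy, Model 1, 3 chains x 1500
recovery_fit <- function() {
  memo("recovery_fit", {
    des <- generate_design(10, 6, seed = 101)
    par <- draw_subject_params(recovery_population(), 10, seed = 102)
    tr <- simulate_trials(des, par, seed = 103)
    suppressWarnings(
      fit_ddm(tr, 1, mcmc_config(3, 1500, 750, seed = 7))
    )
  })
}
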
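# Shared fixtures, memoized so expensive objects are built once per run.

.memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .memo)) assign(key, force(expr), envir = .memo)
  get(key, envir = .memo)
}

# small hierarchy-structured dataset: 6 subjects x 6 trials/cell
small_trials <- function() {
  memo("small_trials", {
    des <- generate_design(6, 6, seed = 301)
    par <- draw_subject_params(ddm_population("hierarchy"), 6, seed = 302)
    simulate_trials(des, par, seed = 303)
  })
}

# quick Model 1 fit on the small dataset (for PPC / feature / LOO tests)
quick_fit <- function() {
  memo("quick_fit", {
    suppressWarnings(
      fit_ddm(small_trials(), 1, mcmc_config(3, 600, 300, seed = 311))
    )
  })
}

# reference WFPT density: long fixed-truncation series evaluated in R,
# independent of the C++ implementation's term selection
ref_wfpt <- function(t, v, a, t0, z, boundary = "upper", K = 300) {
  vapply(t, function(tt) {
    td <- tt - t0
    if (td <= 0) return(0)
    if (boundary == "upper") { v2 <- -v; w <- 1 - z } else { v2 <- v; w <- z }
    u <- td / a^2
    if (u > 0.3) {  # large-time representation
      k <- seq_len(K)
      f <- pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
    } else {        # small-time representation
      k <- -K:K
      f <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * u))) /
        sqrt(2 * pi * u^3)
    }
    max(f, 0) * exp(-v2 * a * w - v2^2 * td / 2) / a^2
  }, 0)
}

# brute-force two-way within-subject sums of squares (balanced designs)
oracle_rm_ss <- function(Y, n_a = 3, n_b = 5) {
  # Y: subjects x (a*b) matrix, columns ordered a-major then b
  n <- nrow(Y)
  arr <- array(t(Y), dim = c(n_b, n_a, n))      # b x a x s
  gm <- mean(arr)
  m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 1, mean)
  m_s <- apply(arr, 3, mean)
  m_ab <- apply(arr, c(1, 2), mean)
  m_as <- apply(arr, c(2, 3), mean)
  m_bs <- apply(arr, c(1, 3), mean)
  ss_a <- n * n_b * sum((m_a - gm)^2)
  ss_b <- n * n_a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_b - gm, m_a - gm, `+`) - gm)^2)
  ss_as <- n_b * sum((m_as - outer(m_a - gm, m_s - gm, `+`) - gm)^2)
  ss_bs <- n_a * sum((m_bs - outer(m_b - gm, m_s - gm, `+`) - gm)^2)
  resid <- arr
  for (s in seq_len(n)) for (aa in seq_len(n_a)) for (bb in seq_len(n_b)) {
    resid[bb, aa, s] <- arr[bb, aa, s] - m_ab[bb, aa] - m_as[aa, s] -
      m_bs[bb, s] + m_a[aa] + m_b[bb] + m_s[s] - gm
  }
  ss_abs <- sum(resid^2)
  list(
    hierarchy = c(ss = ss_a, ss_error = ss_as,
                  F = (ss_a / (n_a - 1)) / (ss_as / ((n_a - 1) * (n - 1)))),
    block = c(ss = ss_b, ss_error = ss_bs,
              F = (ss_b / (n_b - 1)) / (ss_bs / ((n_b - 1) * (n - 1)))),
    interaction = c(ss = ss_ab, ss_error = ss_abs,
                    F = (ss_ab / ((n_a - 1) * (n_b - 1))) /
                      (ss_abs / ((n_a - 1) * (n_b - 1) * (n - 1))))
  )
}

# trial tibble carrying participant x cell means directly (one row per cell)
cellmean_trials <- function(values, dv = "accuracy") {
  # values: subjects x 15 matrix, columns h-major (h1b1..h1b5, h2b1, ...)
  n <- nrow(values)
  g <- tidyr::crossing(participant_id = seq_len(n), rule_hierarchy = 1:3,
                       block = 1:5) |>
    dplyr::arrange(participant_id, rule_hierarchy, block)
  g$trial_index <- rep(seq_len(15), n)
  g$rule_switch <- 0L
  if (dv == "accuracy") {
    g$accuracy <- as.vector(t(values))
    g$rt <- 1
  } else {
    g$accuracy <- 1L
    g$rt <- as.vector(t(values))
  }
  g
}
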
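# Convergence diagnostics, highest-density intervals and posterior
# predictive checks.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio, computed per parameter on
#' post-burn-in draws: with `m` chains of `n` draws, `W` the mean
#' within-chain variance and `B` `n` times the variance of the chain means,
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. The plain estimator can dip
#' slightly below one when the chain means happen to agree more closely
#' than the within-chain spread predicts.
#'
#' @param draws Either an `iterations x chains` matrix (one parameter) or an
#'   `iterations x chains x parameters` array with named parameters.
#' @return A tibble with columns `parameter` and `rhat`.
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) {
    draws <- array(draws, dim = c(dim(draws), 1L),
                   dimnames = list(NULL, NULL, "param"))
  }
  stopifnot(length(dim(draws)) == 3)
  m <- dim(draws)[2]
  n <- dim(draws)[1]
  if (m < 2) rlang::abort("R-hat needs at least 2 chains")
  if (n < 10) rlang::abort("R-hat needs at least 10 retained draws per chain")
  rhat <- vapply(seq_len(dim(draws)[3]), function(k) {
    x <- draws[, , k]
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  tibble::tibble(parameter = dimnames(draws)[[3]], rhat = rhat)
}

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws.
#'
#' @param x Numeric sample (>= 20 values unless degenerate-constant).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  if (length(x) == 0) rlang::abort("empty sample")
  if (mass <= 0 || mass >= 1) rlang::abort("`mass` must lie in (0, 1)")
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m):n] - x[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Are two posteriors credibly different by the HDI non-overlap rule?
#'
#' `TRUE` iff the `mass` highest-density intervals of the two samples are
#' disjoint; intervals sharing an endpoint count as overlapping. Symmetric
#' in its arguments.
#'
#' @param draws_a,draws_b Numeric samples.
#' @param mass HDI mass (default 0.95).
#' @return Logical scalar.
#' @export
hdi_significant <- function(draws_a, draws_b, mass = 0.95) {
  ia <- hdi(draws_a, mass)
  ib <- hdi(draws_b, mass)
  ia[2] < ib[1] || ib[2] < ia[1]
}

#' Posterior predictive check
#'
#' Simulates one replicate dataset at the subject-level posterior means of a
#' fit (same trial counts per participant x design cell as the observed
#' data) and compares, per design cell pooled over participants, the
#' accuracy and the RT quantiles (.1, .3, .5, .7, .9) of observed vs
#' simulated data.
#'
#' @param fit A [fit_ddm()] result.
#' @param trials Observed trial tibble (defaults to the fitted data).
#' @param seed Optional integer seed for the replicate simulation.
#' @return A list of class `ddm_ppc`: `cells` (per-cell tibble),
#'   `max_rt_discrepancy` (max absolute RT-quantile gap, seconds) and
#'   `accuracy_discrepancy`.
#' @export
posterior_predictive_check <- function(fit, trials = fit$trials, seed = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  force(trials)
  if (is.finite(fit$max_rhat) && fit$max_rhat >= 1.05) {
    rlang::warn(sprintf("PPC on a fit with max R-hat %.3f >= 1.05", fit$max_rhat))
  }
  if (!is.null(seed)) set.seed(seed)
  qs <- c(.1, .3, .5, .7, .9)

  params <- fit$subject_means |>
    dplyr::select("participant_id", "parameter", "cell", "estimate") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
  sim <- trials
  cidx <- fit$spec$cell_of(trials$rule_hierarchy, trials$block)
  key <- paste(trials$participant_id, cidx)
  pkey <- paste(params$participant_id, params$cell)
  sim$rt <- NA_real_; sim$accuracy <- NA_integer_
  for (k in unique(key)) {
    idx <- which(key == k)
    pr <- params[match(k, pkey), ]
    if (is.na(pr$participant_id[1])) {
      rlang::warn(paste("PPC: no parameters for cell", k, "- skipped"))
      next
    }
    s <- simulate_fpt_cpp(length(idx), pr$v, pr$a, pr$z, 0.001, 60)
    sim$rt[idx] <- pr$t0 + s$t_dec
    sim$accuracy[idx] <- s$upper
  }

  cell_summary <- function(d, which) {
    d |>
      dplyr::filter(!is.na(.data$rt)) |>
      dplyr::group_by(.data$rule_hierarchy, .data$block) |>
      dplyr::summarise(
        accuracy = mean(.data$accuracy),
        q = list(quantile(.data$rt, qs)),
        .groups = "drop"
      ) |>
      tidyr::unnest_wider("q") |>
      dplyr::mutate(source = which)
  }
  obs <- cell_summary(trials, "observed")
  rep_ <- cell_summary(sim, "simulated")
  qcols <- paste0(qs * 100, "%")
  both <- if (nrow(rep_)) {
    dplyr::inner_join(obs, rep_, by = c("rule_hierarchy", "block"),
                      suffix = c("_obs", "_sim"))
  } else obs[0, ]
  if (nrow(both)) {
    rt_gap <- max(abs(as.matrix(both[paste0(qcols, "_obs")]) -
                      as.matrix(both[paste0(qcols, "_sim")])))
    acc_gap <- max(abs(both$accuracy_obs - both$accuracy_sim))
  } else {
    rt_gap <- NA_real_; acc_gap <- NA_real_
  }
  structure(list(
    cells = dplyr::bind_rows(obs, rep_),
    max_rt_discrepancy = rt_gap,
    accuracy_discrepancy = acc_gap
  ), class = "ddm_ppc")
}

#' @export
print.ddm_ppc <- function(x, ...) {
  cat(sprintf(
    "Posterior predictive check: max |RT quantile gap| = %.3f s, max |accuracy gap| = %.3f\n",
    x$max_rt_discrepancy, x$accuracy_discrepancy))
  invisible(x)
}
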
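# Information criteria and LOO-based comparison of the four model
# structures.  ELPD_loo uses importance sampling from the posterior draws
# with Pareto-smoothed tail weights; the generalized Pareto tail is fitted
# by the Zhang-Stephens profile-posterior method.

#' Akaike / Bayesian information criteria for a hierarchical DDM fit
#'
#' Both use the total log-likelihood at the posterior means of the
#' subject-level parameters (the plug-in deviance):
#' `AIC = 2k - 2 logL`, `BIC = k log(n) - 2 logL`, with `k` the free
#' group-level location count of the model structure.
#'
#' @param fit A [fit_ddm()] result.
#' @param k Free parameter count; defaults to [count_free_params()] of the
#'   fit's model structure.
#' @param n_trials Number of trials for the BIC penalty; defaults to the
#'   fitted trial count.
#' @return A single numeric value.
#' @export
ddm_aic <- function(fit, k = NULL) {
  if (is.null(k)) k <- count_free_params(fit$spec)
  2 * k - 2 * fit$loglik_hat
}

#' @rdname ddm_aic
#' @export
ddm_bic <- function(fit, k = NULL, n_trials = NULL) {
  if (is.null(k)) k <- count_free_params(fit$spec)
  if (is.null(n_trials)) n_trials <- fit$n_trials
  if (n_trials <= 0) rlang::abort("`n_trials` must be positive")
  k * log(n_trials) - 2 * fit$loglik_hat
}

# Zhang & Stephens (2009) profile-posterior fit of the generalized Pareto
# shape to exceedances x > 0; returns c(khat, sigma).
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xq)
  kj <- -vapply(theta, function(th) mean(log1p(-th * x)), 0)
  lj <- n * (log(theta / kj) + kj - 1)
  w <- 1 / vapply(lj, function(l) sum(exp(lj - l)), 0)
  th_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-th_hat * x))
  c(k = k_hat, sigma = k_hat / th_hat)
}

# Pareto-smoothed importance weights from raw log-weights (one observation);
# returns list(log_weights, khat)
.psis_one <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || sd(lw) < 1e-12) {
    return(list(lw = lw, khat = -Inf))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  wt <- exp(lw[tail_ids])
  exceed <- wt - cut
  if (all(exceed <= 0)) return(list(lw = lw, khat = -Inf))
  fitp <- .gpd_fit(exceed[exceed > 0])
  k <- fitp["k"]; sigma <- fitp["sigma"]
  # expected order statistics of the fitted GPD replace the raw tail
  p <- (seq_len(M) - 0.5) / M
  qg <- if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * ((1 - p)^(-k) - 1) / k
  smoothed <- cut + qg
  smoothed <- pmin(smoothed, exp(max(lw)))   # truncate at the raw maximum
  lw[tail_ids[order(wt)]] <- log(smoothed)
  list(lw = lw, khat = unname(k))
}

#' Expected log predictive density by PSIS-LOO
#'
#' Leave-one-out expected log predictive density estimated from posterior
#' draws by importance sampling with Pareto-smoothed weights. The standard
#' error is the standard deviation of the pointwise contributions times
#' `sqrt(n)`. Observations whose Pareto shape exceeds 0.7 are flagged with
#' a reliability warning; the value is still returned.
#'
#' @param fit A [fit_ddm()] result, or a draws x trials pointwise
#'   log-likelihood matrix with at least 100 rows.
#' @return A list of class `ddm_elpd`: `elpd`, `se`, `pointwise` (per-trial
#'   contributions), `khat` (per-trial Pareto shapes), `n_bad` (shapes >
#'   0.7).
#' @export
elpd_loo <- function(fit) {
  ll <- if (inherits(fit, "ddm_fit")) fit$pointwise else as.matrix(fit)
  S <- nrow(ll); n <- ncol(ll)
  if (S < 100) rlang::abort("ELPD_loo needs at least 100 retained draws")
  pw <- numeric(n); khat <- numeric(n)
  for (i in seq_len(n)) {
    li <- ll[, i]
    ps <- .psis_one(-li)             # raw log ratio = -loglik
    lwn <- ps$lw - .logsumexp(ps$lw) # normalized log weights
    pw[i] <- .logsumexp(lwn + li)
    khat[i] <- ps$khat
  }
  n_bad <- sum(khat > 0.7)
  if (n_bad > 0) {
    rlang::warn(sprintf(
      "PSIS-LOO: %d of %d observations have Pareto k-hat > 0.7; estimates may be unreliable",
      n_bad, n))
  }
  structure(list(elpd = sum(pw), se = sd(pw) * sqrt(n),
                 pointwise = pw, khat = khat, n_bad = n_bad),
            class = "ddm_elpd")
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.ddm_elpd <- function(x, ...) {
  cat(sprintf("ELPD_loo = %.2f +/- %.2f (n = %d, %d unreliable)\n",
              x$elpd, x$se, length(x$pointwise), x$n_bad))
  invisible(x)
}

#' Compare competing hierarchical DDM fits
#'
#' Builds the comparison table (free parameters, AIC, BIC, max R-hat,
#' ELPD_loo with standard error) and all pairwise ELPD differences, with
#' `se(delta)` computed from the pointwise ELPD differences (never from the
#' two standard errors in quadrature). A pairwise difference is flagged
#' significant iff `delta > 2 * se(delta)`. The selected model is the one
#' with the lowest AIC among converged fits (max R-hat < 1.05).
#'
#' @param fits A list of [fit_ddm()] results on identical data.
#' @return A list of class `ddm_comparison`: `table`, `pairwise`,
#'   `selected` (model id).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "ddm_fit")))
  n <- vapply(fits, `[[`, 0L, "n_trials")
  if (length(unique(n)) != 1) {
    rlang::abort("fits must be on identical trial sets")
  }
  rts <- lapply(fits, function(f) f$trials$rt)
  if (!all(vapply(rts, identical, TRUE, rts[[1]]))) {
    rlang::abort("fits must be on identical trial sets")
  }

  loos <- lapply(fits, elpd_loo)
  tab <- tibble::tibble(
    model_id = vapply(fits, function(f) f$spec$model_id, 0L),
    label = vapply(fits, function(f) f$spec$label, ""),
    k = vapply(fits, function(f) count_free_params(f$spec), 0L),
    aic = vapply(fits, ddm_aic, 0),
    bic = vapply(fits, ddm_bic, 0),
    max_rhat = vapply(fits, `[[`, 0, "max_rhat"),
    elpd_loo = vapply(loos, `[[`, 0, "elpd"),
    elpd_se = vapply(loos, `[[`, 0, "se")
  )

  pairs <- list()
  idx <- seq_along(fits)
  for (i in idx) for (j in idx) {
    if (i >= j) next
    d <- loos[[i]]$pointwise - loos[[j]]$pointwise
    delta <- sum(d)
    se_d <- sd(d) * sqrt(length(d))
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      model_a = tab$model_id[i], model_b = tab$model_id[j],
      delta_elpd = delta, se_delta = se_d,
      significant = abs(delta) > 2 * se_d
    )
  }
  pairwise <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(model_a = integer(), model_b = integer(),
                   delta_elpd = numeric(), se_delta = numeric(),
                   significant = logical())

  converged <- tab$max_rhat < 1.05
  pool <- if (any(converged)) which(converged) else seq_len(nrow(tab))
  if (!any(converged)) rlang::warn("no fit converged (max R-hat >= 1.05); selecting by AIC anyway")
  selected <- tab$model_id[pool[which.min(tab$aic[pool])]]

  structure(list(table = tab, pairwise = pairwise, selected = selected),
            class = "ddm_comparison")
}

#' @export
print.ddm_comparison <- function(x, ...) {
  cat("Model comparison (selected: model", x$selected, ")\n")
  print(as.data.frame(x$table), digits = 5)
  invisible(x)
}
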
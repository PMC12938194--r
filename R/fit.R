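# Hierarchical Bayesian estimation by adaptive component-wise random-walk
# Metropolis-Hastings.  Subject-level parameters follow the model's factor
# structure (per hierarchy, per block, additive, or cell-wise), drawn
# around group-level means; hyperpriors are uniform on bounded supports.
# Proposals walk on unconstrained transforms (identity for v, log for a and
# scales, logit for z, range-logit for t0), with Jacobian terms in the
# acceptance ratio.  Two structural moves - a joint group translation
# (mean and subjects together) and a joint dilation (scale and subject
# deviations together) - decouple the centred hierarchy so short chains
# mix.  Every adapt_window iterations during burn-in each component
# family's step size is multiplied by exp(+/-0.1) according to whether its
# local acceptance sits above or below the target; step sizes are frozen
# after burn-in.

#' MCMC configuration
#'
#' @param n_chains Number of independent chains (default 3).
#' @param n_iter Total iterations per chain (default 3000).
#' @param burn_in Burn-in iterations discarded from every summary
#'   (default 1500; must be < `n_iter`).
#' @param adapt_window Iterations between step-size adaptations
#'   (default 200).
#' @param target_accept Target local acceptance rate (default 0.30).
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param eps Truncation tolerance of the first-passage density series.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 3000L, burn_in = 1500L,
                        adapt_window = 200L, target_accept = 0.30,
                        seed = 1L, eps = 1e-7) {
  if (burn_in >= n_iter) rlang::abort("`burn_in` must be < `n_iter`")
  if (target_accept <= 0 || target_accept >= 1) {
    rlang::abort("`target_accept` must lie in (0, 1)")
  }
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 adapt_window = as.integer(adapt_window),
                 target_accept = target_accept, seed = as.integer(seed),
                 eps = eps),
            class = "mcmc_config")
}

.PARAMS <- c("v", "a", "t0", "z")

# truncated-normal log density with guard against vanishing mass
.ld_tnorm <- function(x, mu, sigma, lo, hi) {
  zden <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
  out <- dnorm(x, mu, sigma, log = TRUE) - log(pmax(zden, 1e-300))
  out[x < lo | x > hi] <- -Inf
  out
}

# EZ-style moment initializer for one pooled cell of trials
.ez_init <- function(rt, acc) {
  n <- length(rt)
  pc <- (sum(acc) + 0.5) / (n + 1)            # edge-corrected accuracy
  pc <- min(max(pc, 0.55), 0.98)
  rtc <- rt[acc == 1]
  if (length(rtc) < 3) rtc <- rt
  vrt <- max(var(rtc), 1e-3)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * abs(x)^0.25
  v <- min(max(v, 0.05), 3)
  a <- min(max(L / v, 0.8), 8)
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- mean(rtc) - mdt
  t0 <- min(max(t0, 0.05), 0.9 * min(rt), 2.5)
  c(v = v, a = a, t0 = t0, z = 0.45)
}

#' Fit a hierarchical drift-diffusion model
#'
#' Estimates group-level cell means and pooled scales, plus subject-level
#' parameters, for one of the four model structures, by adaptive
#' random-walk Metropolis-Hastings (see [mcmc_config()]). Group-level
#' draws, a pointwise log-likelihood matrix for information criteria and
#' LOO, Gelman-Rubin diagnostics and the acceptance history are returned.
#'
#' Subject-level parameters mirror the model's factor map: one value per
#' hierarchy (Model 1), per block (Model 2), hierarchy baseline plus
#' zero-sum block offsets (Model 3), or one per cell (Model 4) - so an
#' additive model genuinely cannot express an interaction at any level.
#'
#' @param trials A trial tibble with columns `participant_id`, `block`,
#'   `rule_hierarchy`, `rt` (seconds), `accuracy` (0/1).
#' @param model A model id 1-4 or a [model_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `ddm_fit`.
#' @export
fit_ddm <- function(trials, model = 1, config = mcmc_config()) {
  spec <- if (inherits(model, "ddm_model_spec")) model else model_spec(model)
  stopifnot(inherits(config, "mcmc_config"))
  need <- c("participant_id", "block", "rule_hierarchy", "rt", "accuracy")
  if (!all(need %in% names(trials))) {
    rlang::abort(paste("trials must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(trials) == 0) rlang::abort("empty trial table")
  if (var(trials$rt) == 0) rlang::abort("degenerate data: constant RT column")

  subjects <- sort(unique(trials$participant_id))
  ns <- length(subjects)
  nc <- spec$n_cells
  sidx <- match(trials$participant_id, subjects)
  cidx <- spec$cell_of(trials$rule_hierarchy, trials$block)
  grp <- (sidx - 1L) * nc + cidx
  n_groups <- ns * nc
  if (length(unique(grp)) < n_groups) {
    rlang::abort("configuration error: some participant x cell has no trials")
  }
  rt <- as.numeric(trials$rt)
  acc <- as.integer(trials$accuracy)

  bounds <- ddm_param_bounds()
  bl <- setNames(bounds$lower, bounds$parameter)
  bu <- setNames(bounds$upper, bounds$parameter)
  half_range <- (bu - bl) / 2

  # per-(subject, cell) t0 upper bound: below the cell's minimum RT
  minrt <- tapply(rt, grp, min)
  Ut0 <- matrix(pmin(bu["t0"],
                     as.numeric(minrt[as.character(seq_len(n_groups))]) - 1e-4),
                nrow = ns, ncol = nc, byrow = TRUE)
  if (any(Ut0 <= bl["t0"] + 1e-3)) {
    rlang::abort("some participant x cell has minimum RT too small to admit a non-decision time")
  }

  # pooled-cell moment initializer
  init_cell <- t(vapply(seq_len(nc), function(cc) {
    sel <- cidx == cc
    .ez_init(rt[sel], acc[sel])
  }, numeric(4)))
  colnames(init_cell) <- .PARAMS

  # the t0 constraint applies to the group-level mean as well (else the
  # hyper-mean is unidentified above the subject-level truncation).  The
  # bound is computed per hierarchy where the model's cells carry one, so
  # competing structures share identical mean supports within a hierarchy
  # and block-resolved structures gain nothing from sitting against their
  # own cells' faster minima.
  mu_hi_t0 <- vapply(seq_len(nc), function(cc) {
    h <- spec$cells$rule_hierarchy[cc]
    sel <- if (is.na(h)) cidx == cc else
      trials$rule_hierarchy == h
    min(bu["t0"], min(rt[sel]) - 1e-4)
  }, 0)
  init_cell[, "t0"] <- pmin(init_cell[, "t0"], 0.9 * mu_hi_t0)

  sdg <- spec$sd_group                   # sd-pool index per cell
  sdg_ids <- sort(unique(sdg))
  nsg <- length(sdg_ids)
  sd_of_cell <- match(sdg, sdg_ids)

  hb <- spec$cells                        # cell table (h, b, labels)
  h_of_cell <- hb$rule_hierarchy
  b_of_cell <- hb$block

  # scale priors: uniform on (0, half the mean range]; for t0 the mean
  # range is effectively bounded by the minimum observed RT, so the cap
  # follows the data rather than the nominal [0.01, 3] support
  half_range["t0"] <- (max(mu_hi_t0) - bl["t0"]) / 2

  env <- list(spec = spec, cfg = config, rt = rt, acc = acc, grp = grp,
              ns = ns, nc = nc, n_groups = n_groups, bl = bl, bu = bu,
              half_range = half_range, Ut0 = Ut0, mu_hi_t0 = mu_hi_t0,
              init_cell = init_cell, sd_of_cell = sd_of_cell, nsg = nsg,
              h_of_cell = h_of_cell, b_of_cell = b_of_cell)
  runner <- if (spec$additive) .run_chain_additive else .run_chain
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    chains[[ch]] <- runner(env)
  }

  n_ret <- config$n_iter - config$burn_in
  par_names <- colnames(chains[[1]]$draws)
  draws <- array(NA_real_, dim = c(n_ret, config$n_chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(config$n_chains)) draws[, ch, ] <- chains[[ch]]$draws

  pointwise <- do.call(rbind, lapply(chains, `[[`, "pointwise"))
  accept <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    chains[[ch]]$accept |> dplyr::mutate(chain = ch, .before = 1)
  }))

  # subject posterior means per cell (averaged over chains)
  subj_mean <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    Reduce(`+`, lapply(chains, function(ch) ch$subj_sum[[p]])) /
      (n_ret * config$n_chains)
  })
  subject_means <- dplyr::bind_rows(lapply(seq_along(.PARAMS), function(k) {
    m <- subj_mean[[k]]
    tibble::tibble(
      participant_id = rep(subjects, nc),
      cell = rep(seq_len(nc), each = ns),
      parameter = .PARAMS[k],
      estimate = as.vector(m)
    )
  })) |>
    dplyr::left_join(hb, by = "cell") |>
    dplyr::select("participant_id", "parameter", "cell", "rule_hierarchy",
                  "block", "label", "estimate")

  rhat <- if (config$n_chains >= 2) gelman_rubin(draws) else
    tibble::tibble(parameter = par_names, rhat = NA_real_)

  # plug-in log-likelihood for AIC/BIC: the group-level cell values only
  # (exactly the k location parameters the criteria count, so
  # subject-level flexibility cannot inflate the fit), maximized over the
  # retained draws - a stable proxy for the constrained ML that does not
  # inherit posterior-mean Monte-Carlo noise
  cell_draws <- .group_cell_draws(spec, draws)
  per_draw <- rowSums(pointwise_loglik_cpp(
    rt, acc, cidx, cell_draws$v, cell_draws$a, cell_draws$t0,
    cell_draws$z, config$eps
  ))
  loglik_hat <- max(per_draw)

  fit <- structure(list(
    spec = spec, config = config, draws = draws,
    subject_means = subject_means, pointwise = pointwise,
    rhat = rhat, max_rhat = suppressWarnings(max(rhat$rhat, na.rm = TRUE)),
    acceptance = accept, loglik_hat = loglik_hat,
    n_trials = length(rt), subjects = subjects,
    trials = trials
  ), class = "ddm_fit")
  if (is.finite(fit$max_rhat) && fit$max_rhat >= 1.05) {
    rlang::warn(sprintf(
      "max R-hat = %.3f >= 1.05: chains may not have converged (stricter reference: 1.01)",
      fit$max_rhat))
  }
  fit
}

# per-draw group-level cell values (draws x n_cells per parameter) from
# the flattened draws array; reconstructs additive cells from baselines
# and zero-sum offsets
.group_cell_draws <- function(spec, draws) {
  flat <- matrix(draws, nrow = dim(draws)[1] * dim(draws)[2],
                 dimnames = list(NULL, dimnames(draws)[[3]]))
  out <- list()
  for (p in .PARAMS) {
    if (!spec$additive) {
      out[[p]] <- flat[, paste0(p, "[", spec$cells$label, "]"), drop = FALSE]
    } else {
      al <- flat[, paste0(p, "[h", 1:3, "]"), drop = FALSE]
      be4 <- flat[, paste0(p, "[bdev", 1:4, "]"), drop = FALSE]
      be <- cbind(be4, -rowSums(be4))
      out[[p]] <- al[, spec$cells$rule_hierarchy, drop = FALSE] +
        be[, spec$cells$block, drop = FALSE]
    }
  }
  out
}

# shared window bookkeeping: rate columns by component family
.accept_row <- function(it, phase, win_acc, win_n, cnt, fam) {
  fam_rate <- function(keys) {
    a <- sum(vapply(keys, function(k) sum(cnt[[paste0(k, "_a")]]), 0))
    n <- sum(vapply(keys, function(k) sum(cnt[[paste0(k, "_n")]]), 0))
    a / max(n, 1)
  }
  tibble::tibble(window_end = it, phase = phase,
                 rate = win_acc / max(win_n, 1),
                 rate_subject = fam_rate(fam$subject),
                 rate_group_mean = fam_rate(fam$mean),
                 rate_group_sd = fam_rate(fam$sd))
}

# ---------------------------------------------------------------------------
# chain sampler for factor-map models with one free mean per cell
# (Models 1, 2, 4)
.run_chain <- function(env) {
  spec <- env$spec; cfg <- env$cfg
  rt <- env$rt; acc <- env$acc; grp <- env$grp
  ns <- env$ns; nc <- env$nc; n_groups <- env$n_groups
  bl <- env$bl; bu <- env$bu; half_range <- env$half_range
  Ut0 <- env$Ut0; mu_hi_t0 <- env$mu_hi_t0; init_cell <- env$init_cell
  sd_of_cell <- env$sd_of_cell; nsg <- env$nsg
  eps <- cfg$eps; target <- cfg$target_accept

  mu_hi <- list(v = rep(bu["v"], nc), a = rep(bu["a"], nc),
                t0 = env$mu_hi_t0, z = rep(bu["z"], nc))

  # ---- initial state (jittered per chain for over-dispersion) ----
  jit <- function(x, f, lo, hi) pmin(pmax(x * exp(rnorm(length(x), 0, f)), lo + 1e-6), hi - 1e-6)
  mu <- list(
    v = jit(init_cell[, "v"], 0.15, bl["v"], bu["v"]),
    a = jit(init_cell[, "a"], 0.15, bl["a"], bu["a"]),
    t0 = pmin(jit(init_cell[, "t0"], 0.10, bl["t0"], bu["t0"]),
              0.95 * mu_hi_t0),
    z = jit(init_cell[, "z"], 0.10, bl["z"], bu["z"])
  )
  sig <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    rep(min(max(0.12 * mean(abs(mu[[p]])), 0.03), half_range[p] * 0.5), nsg)
  })
  X <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    m <- matrix(rep(mu[[p]], each = ns), nrow = ns)
    m * exp(matrix(rnorm(ns * nc, 0, 0.03), ns, nc))
  })
  X$v <- pmin(pmax(X$v, bl["v"] + 0.01), bu["v"] - 0.01)
  X$a <- pmin(pmax(X$a, bl["a"] + 0.01), bu["a"] - 0.01)
  X$z <- pmin(pmax(X$z, bl["z"] + 0.005), bu["z"] - 0.005)
  X$t0 <- pmin(pmax(X$t0, bl["t0"] + 0.005), Ut0 * 0.9)

  vec <- function(m) as.vector(t(m))   # row-major: group index (s-1)*nc + c
  ll_groups <- function(Xl) {
    wfpt_loglik_groups_cpp(rt, acc, grp, n_groups,
                           vec(Xl$v), vec(Xl$a), vec(Xl$t0), vec(Xl$z), eps)
  }
  llg <- ll_groups(X)

  sub_lo <- list(v = bl["v"], a = bl["a"], t0 = bl["t0"], z = bl["z"])
  sub_hi <- list(v = bu["v"], a = bu["a"], t0 = NULL, z = bu["z"]) # t0: Ut0

  # step sizes per component family (on the proposal scales)
  st_subj <- matrix(c(0.6, 0.2, 0.4, 0.4), 4, nc, dimnames = list(.PARAMS, NULL))
  st_mu <- matrix(c(0.15, 0.3, 0.05, 0.08), 4, nc, dimnames = list(.PARAMS, NULL))
  st_sd <- matrix(0.7, 4, nsg, dimnames = list(.PARAMS, NULL))
  st_shift <- matrix(c(0.2, 0.3, 0.06, 0.08), 4, nc,
                     dimnames = list(.PARAMS, NULL))
  st_scale <- matrix(0.55, 4, nsg, dimnames = list(.PARAMS, NULL))

  zero2 <- function(m) m * 0
  cnt <- list(subj_a = zero2(st_subj), subj_n = zero2(st_subj),
              mu_a = zero2(st_mu), mu_n = zero2(st_mu),
              sd_a = zero2(st_sd), sd_n = zero2(st_sd),
              sh_a = zero2(st_shift), sh_n = zero2(st_shift),
              dl_a = zero2(st_scale), dl_n = zero2(st_scale),
              gb_a = zero2(st_sd), gb_n = zero2(st_sd))
  fam <- list(subject = "subj", mean = c("mu", "sh"), sd = c("sd", "dl"))

  n_ret <- cfg$n_iter - cfg$burn_in
  mean_names <- unlist(lapply(.PARAMS, function(p)
    paste0(p, "[", spec$cells$label, "]")))
  sd_names <- unlist(lapply(.PARAMS, function(p)
    paste0("sd_", p, "[", seq_len(nsg), "]")))
  draws <- matrix(NA_real_, n_ret, length(mean_names) + length(sd_names),
                  dimnames = list(NULL, c(mean_names, sd_names)))
  pointwise <- matrix(NA_real_, n_ret, length(rt))
  subj_sum <- lapply(setNames(.PARAMS, .PARAMS), function(p) matrix(0, ns, nc))

  accept_hist <- list()
  win_acc <- 0; win_n <- 0
  sig_cell <- function(p) sig[[p]][sd_of_cell]

  for (it in seq_len(cfg$n_iter)) {
    ## ---- subject-level updates, one diffusion parameter at a time ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      x <- X[[p]]
      stepm <- matrix(rep(st_subj[k, ], each = ns), ns, nc)
      noise <- matrix(rnorm(ns * nc), ns, nc) * stepm
      if (p == "v") {
        xn <- x + noise
        lj0 <- 0; lj1 <- 0
      } else if (p == "a") {
        tn <- log(x) + noise
        xn <- exp(tn)
        lj0 <- log(x); lj1 <- tn
      } else if (p == "z") {
        tn <- qlogis(x) + noise
        xn <- plogis(tn)
        lj0 <- log(x * (1 - x)); lj1 <- log(xn * (1 - xn))
      } else { # t0: logit on (lo, Ut0)
        lo <- bl["t0"]; w <- (x - lo) / (Ut0 - lo)
        tn <- qlogis(w) + noise
        wn <- plogis(tn)
        xn <- lo + (Ut0 - lo) * wn
        lj0 <- log((Ut0 - lo) * w * (1 - w))
        lj1 <- log((Ut0 - lo) * wn * (1 - wn))
      }
      Xn <- X; Xn[[p]] <- xn
      lln <- ll_groups(Xn)
      mcell <- matrix(rep(mu[[p]], each = ns), ns, nc)
      scell <- matrix(rep(sig_cell(p), each = ns), ns, nc)
      if (p == "t0") {
        lp0 <- .ld_tnorm(x, mcell, scell, sub_lo$t0, Ut0)
        lp1 <- .ld_tnorm(xn, mcell, scell, sub_lo$t0, Ut0)
      } else {
        lp0 <- .ld_tnorm(x, mcell, scell, sub_lo[[p]], sub_hi[[p]])
        lp1 <- .ld_tnorm(xn, mcell, scell, sub_lo[[p]], sub_hi[[p]])
      }
      dll <- matrix(lln - llg, ns, nc, byrow = TRUE)
      ratio <- dll + (lp1 - lp0) + (lj1 - lj0)
      accm <- matrix(log(runif(ns * nc)), ns, nc) < ratio
      accm[!is.finite(ratio)] <- FALSE
      if (any(accm)) {
        x[accm] <- xn[accm]
        X[[p]] <- x
        gidx <- which(t(accm))
        llg[gidx] <- lln[gidx]
      }
      cnt$subj_a[k, ] <- cnt$subj_a[k, ] + colSums(accm)
      cnt$subj_n[k, ] <- cnt$subj_n[k, ] + ns
      win_acc <- win_acc + sum(accm); win_n <- win_n + ns * nc
    }

    ## ---- group-level location updates (per cell) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      x <- X[[p]]
      scell <- matrix(rep(sig_cell(p), each = ns), ns, nc)
      lo_m <- if (p == "t0") sub_lo$t0 else sub_lo[[p]]
      hi_m <- if (p == "t0") Ut0 else sub_hi[[p]]
      prop <- mu[[p]] + rnorm(nc) * st_mu[k, ]
      ok <- prop > bl[p] & prop < mu_hi[[p]]
      m0 <- matrix(rep(mu[[p]], each = ns), ns, nc)
      m1 <- matrix(rep(prop, each = ns), ns, nc)
      r <- colSums(.ld_tnorm(x, m1, scell, lo_m, hi_m)) -
        colSums(.ld_tnorm(x, m0, scell, lo_m, hi_m))
      accv <- ok & log(runif(nc)) < r & is.finite(r)
      mu[[p]][accv] <- prop[accv]
      cnt$mu_a[k, ] <- cnt$mu_a[k, ] + accv
      cnt$mu_n[k, ] <- cnt$mu_n[k, ] + 1
      win_acc <- win_acc + sum(accv); win_n <- win_n + nc
    }

    ## ---- group-level scale updates (pooled) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      x <- X[[p]]
      mcell <- matrix(rep(mu[[p]], each = ns), ns, nc)
      lo_m <- if (p == "t0") sub_lo$t0 else sub_lo[[p]]
      hi_m <- if (p == "t0") Ut0 else sub_hi[[p]]
      prop <- sig[[p]] * exp(rnorm(nsg) * st_sd[k, ])
      ok <- prop > 0 & prop <= half_range[p]
      s0 <- matrix(rep(sig[[p]][sd_of_cell], each = ns), ns, nc)
      s1 <- matrix(rep(prop[sd_of_cell], each = ns), ns, nc)
      d <- .ld_tnorm(x, mcell, s1, lo_m, hi_m) -
        .ld_tnorm(x, mcell, s0, lo_m, hi_m)
      by_g <- function(m) vapply(seq_len(nsg), function(g)
        sum(m[, sd_of_cell == g, drop = FALSE]), 0)
      r <- by_g(d) + (log(prop) - log(sig[[p]])) # log-scale Jacobian
      accv <- ok & log(runif(nsg)) < r & is.finite(r)
      sig[[p]][accv] <- prop[accv]
      cnt$sd_a[k, ] <- cnt$sd_a[k, ] + accv
      cnt$sd_n[k, ] <- cnt$sd_n[k, ] + 1
      win_acc <- win_acc + sum(accv); win_n <- win_n + nsg
    }

    ## ---- scale jumps: Metropolized approximate Gibbs ----
    # propose sigma^2 from its inverse-gamma conditional (exact but for the
    # truncation normalizers, which enter the acceptance ratio); jumps the
    # scale across diffuse/concentrated regions in one step
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      x <- X[[p]]
      mcell <- matrix(rep(mu[[p]], each = ns), ns, nc)
      lo_m <- if (p == "t0") sub_lo$t0 else sub_lo[[p]]
      hi_m <- if (p == "t0") Ut0 else sub_hi[[p]]
      dev2 <- (x - mcell)^2
      SSg <- vapply(seq_len(nsg), function(g)
        sum(dev2[, sd_of_cell == g, drop = FALSE]), 0)
      mg <- ns * vapply(seq_len(nsg), function(g) sum(sd_of_cell == g), 0)
      prop <- sqrt((SSg / 2) / rgamma(nsg, shape = (mg - 1) / 2))
      ok <- is.finite(prop) & prop > 0 & prop <= half_range[p]
      s0 <- matrix(rep(sig[[p]][sd_of_cell], each = ns), ns, nc)
      s1 <- matrix(rep(prop[sd_of_cell], each = ns), ns, nc)
      lz0 <- log(pmax(pnorm(hi_m, mcell, s0) - pnorm(lo_m, mcell, s0), 1e-300))
      lz1 <- log(pmax(pnorm(hi_m, mcell, s1) - pnorm(lo_m, mcell, s1), 1e-300))
      dzc <- colSums(lz0 - lz1)
      by_g <- function(v) vapply(seq_len(nsg), function(g)
        sum(v[sd_of_cell == g]), 0)
      r <- by_g(dzc)
      accv <- ok & log(runif(nsg)) < r & is.finite(r)
      sig[[p]][accv] <- prop[accv]
      # bookkept apart from the tuned random-walk families: this move has
      # no step size and its acceptance is not what adaptation targets
      cnt$gb_a[k, ] <- cnt$gb_a[k, ] + accv
      cnt$gb_n[k, ] <- cnt$gb_n[k, ] + 1
    }

    ## ---- group translation moves (mean + subjects shifted jointly) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      x <- X[[p]]
      scell <- matrix(rep(sig_cell(p), each = ns), ns, nc)
      lo_m <- if (p == "t0") sub_lo$t0 else sub_lo[[p]]
      hi_m <- if (p == "t0") Ut0 else sub_hi[[p]]
      lz <- function(mcell) log(pmax(
        pnorm(hi_m, mcell, scell) - pnorm(lo_m, mcell, scell), 1e-300))
      delta <- rnorm(nc) * st_shift[k, ]
      mu_new <- mu[[p]] + delta
      xn <- x + matrix(rep(delta, each = ns), ns, nc)
      ok <- mu_new > bl[p] & mu_new < mu_hi[[p]] &
        (colSums(xn > lo_m & xn < hi_m) == ns)
      Xn <- X; Xn[[p]] <- xn
      lln <- ll_groups(Xn)
      dll <- colSums(matrix(lln - llg, ns, nc, byrow = TRUE))
      m0 <- matrix(rep(mu[[p]], each = ns), ns, nc)
      m1 <- matrix(rep(mu_new, each = ns), ns, nc)
      dz <- colSums(lz(m0) - lz(m1))
      r <- dll + dz
      accv <- ok & log(runif(nc)) < r & is.finite(r)
      if (any(accv)) {
        x[, accv] <- xn[, accv]
        X[[p]] <- x
        mu[[p]][accv] <- mu_new[accv]
        gsel <- as.vector(t(matrix(accv, ns, nc, byrow = TRUE)))
        llg[gsel] <- lln[gsel]
      }
      cnt$sh_a[k, ] <- cnt$sh_a[k, ] + accv
      cnt$sh_n[k, ] <- cnt$sh_n[k, ] + 1
      win_acc <- win_acc + sum(accv); win_n <- win_n + nc
    }

    ## ---- group dilation moves (scale + subject deviations jointly) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      x <- X[[p]]
      mcell <- matrix(rep(mu[[p]], each = ns), ns, nc)
      lo_m <- if (p == "t0") sub_lo$t0 else sub_lo[[p]]
      hi_m <- if (p == "t0") Ut0 else sub_hi[[p]]
      dl <- rnorm(nsg) * st_scale[k, ]
      fac <- exp(dl)
      sig_new <- sig[[p]] * fac
      fcol <- fac[sd_of_cell]
      xn <- mcell + (x - mcell) * matrix(rep(fcol, each = ns), ns, nc)
      okc <- (colSums(xn > lo_m & xn < hi_m) == ns)
      ok <- vapply(seq_len(nsg), function(g) all(okc[sd_of_cell == g]), TRUE) &
        sig_new > 0 & sig_new <= half_range[p]
      Xn <- X; Xn[[p]] <- xn
      lln <- ll_groups(Xn)
      dllc <- colSums(matrix(lln - llg, ns, nc, byrow = TRUE))
      s0 <- matrix(rep(sig[[p]][sd_of_cell], each = ns), ns, nc)
      s1 <- matrix(rep(sig_new[sd_of_cell], each = ns), ns, nc)
      lz0 <- log(pmax(pnorm(hi_m, mcell, s0) - pnorm(lo_m, mcell, s0), 1e-300))
      lz1 <- log(pmax(pnorm(hi_m, mcell, s1) - pnorm(lo_m, mcell, s1), 1e-300))
      dzc <- colSums(lz0 - lz1)
      by_g <- function(v) vapply(seq_len(nsg), function(g)
        sum(v[sd_of_cell == g]), 0)
      r <- by_g(dllc) + by_g(dzc) + dl
      accv <- ok & log(runif(nsg)) < r & is.finite(r)
      if (any(accv)) {
        csel <- sd_of_cell %in% which(accv)
        x[, csel] <- xn[, csel]
        X[[p]] <- x
        sig[[p]][accv] <- sig_new[accv]
        gsel <- as.vector(t(matrix(csel, ns, nc, byrow = TRUE)))
        llg[gsel] <- lln[gsel]
      }
      cnt$dl_a[k, ] <- cnt$dl_a[k, ] + accv
      cnt$dl_n[k, ] <- cnt$dl_n[k, ] + 1
      win_acc <- win_acc + sum(accv); win_n <- win_n + nsg
    }

    ## ---- adaptation & window bookkeeping ----
    if (it %% cfg$adapt_window == 0) {
      phase <- if (it <= cfg$burn_in) "burnin" else "sampling"
      accept_hist[[length(accept_hist) + 1]] <-
        .accept_row(it, phase, win_acc, win_n, cnt, fam)
      if (it < cfg$burn_in) {
        tune <- function(st, a, n) st * exp(ifelse(a / pmax(n, 1) > target, 0.1, -0.1))
        st_subj <- tune(st_subj, cnt$subj_a, cnt$subj_n)
        st_mu <- tune(st_mu, cnt$mu_a, cnt$mu_n)
        st_sd <- tune(st_sd, cnt$sd_a, cnt$sd_n)
        st_shift <- tune(st_shift, cnt$sh_a, cnt$sh_n)
        st_scale <- tune(st_scale, cnt$dl_a, cnt$dl_n)
      }
      cnt <- lapply(cnt, function(m) m * 0)
      win_acc <- 0; win_n <- 0
    }

    ## ---- record ----
    if (it > cfg$burn_in) {
      j <- it - cfg$burn_in
      draws[j, ] <- c(unlist(mu, use.names = FALSE),
                      unlist(sig, use.names = FALSE))
      pointwise[j, ] <- wfpt_loglik_trials_cpp(
        rt, acc, vec(X$v)[grp], vec(X$a)[grp], vec(X$t0)[grp], vec(X$z)[grp],
        eps)
      for (p in .PARAMS) subj_sum[[p]] <- subj_sum[[p]] + X[[p]]
    }
  }

  list(draws = draws, pointwise = pointwise,
       accept = dplyr::bind_rows(accept_hist), subj_sum = subj_sum)
}

# ---------------------------------------------------------------------------
# chain sampler for the additive model (Model 3): subject-level parameters
# are hierarchy baselines plus zero-sum block offsets, so neither the group
# level nor the subject level can express an interaction.  Subject effects
# carry plain normal priors with an admissibility indicator on the implied
# cell values (truncation mass is negligible away from the bounds).
.run_chain_additive <- function(env) {
  spec <- env$spec; cfg <- env$cfg
  rt <- env$rt; acc <- env$acc; grp <- env$grp
  ns <- env$ns; nc <- env$nc; n_groups <- env$n_groups
  bl <- env$bl; bu <- env$bu; half_range <- env$half_range
  Ut0 <- env$Ut0; mu_hi_t0 <- env$mu_hi_t0; init_cell <- env$init_cell
  h_of_cell <- env$h_of_cell; b_of_cell <- env$b_of_cell
  eps <- cfg$eps; target <- cfg$target_accept

  lo_cell <- function(p) bl[p]
  hi_cell <- function(p) if (p == "t0") Ut0 else
    matrix(bu[p], ns, nc)
  mu_hi <- list(v = rep(bu["v"], nc), a = rep(bu["a"], nc),
                t0 = mu_hi_t0, z = rep(bu["z"], nc))

  # ---- initial state ----
  jit <- function(x, f, lo, hi) pmin(pmax(x * exp(rnorm(length(x), 0, f)), lo + 1e-6), hi - 1e-6)
  A <- list(); B <- list()
  for (p in .PARAMS) {
    ah <- vapply(1:3, function(h) mean(init_cell[h_of_cell == h, p]), 0)
    bb <- vapply(1:5, function(b) mean(init_cell[b_of_cell == b, p]), 0)
    bb <- bb - mean(bb)
    A[[p]] <- jit(ah, 0.1, bl[p], bu[p])
    B[[p]] <- bb
    # shrink offsets until every implied cell mean is admissible
    while (TRUE) {
      cmv <- A[[p]][h_of_cell] + B[[p]][b_of_cell]
      if (all(cmv > bl[p] & cmv < mu_hi[[p]])) break
      B[[p]] <- B[[p]] * 0.5
      if (max(abs(B[[p]])) < 1e-8) {
        A[[p]] <- pmin(pmax(A[[p]], bl[p] + 0.01), min(mu_hi[[p]]) - 0.01)
        B[[p]] <- rep(0, 5)
        break
      }
    }
  }
  cmu <- function(p) A[[p]][h_of_cell] + B[[p]][b_of_cell]

  sigA <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    rep(min(max(0.12 * mean(abs(A[[p]])), 0.03), half_range[p] * 0.5), 3)
  })
  sigB <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    min(max(0.05 * mean(abs(A[[p]])), 0.02), half_range[p] * 0.5)
  })

  # subject effects: As (ns x 3 baselines), Bs (ns x 5, rows sum to zero)
  As <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    matrix(rep(A[[p]], each = ns), ns, 3) +
      matrix(rnorm(ns * 3, 0, sigA[[p]][1] / 2), ns, 3)
  })
  Bs <- lapply(setNames(.PARAMS, .PARAMS), function(p) {
    m <- matrix(rep(B[[p]], each = ns), ns, 5)
    m - rowMeans(m)
  })
  comp <- function(p) As[[p]][, h_of_cell] + Bs[[p]][, b_of_cell]
  # nudge inadmissible starts toward the group baseline
  for (p in .PARAMS) {
    for (rep_i in 1:30) {
      Xp <- comp(p)
      bad <- rowSums(Xp <= lo_cell(p) | Xp >= hi_cell(p)) > 0
      if (p == "t0") bad <- bad | rowSums(Xp >= Ut0) > 0
      if (!any(bad)) break
      As[[p]][bad, ] <- 0.7 * As[[p]][bad, ] +
        0.3 * matrix(rep(A[[p]], each = sum(bad)), sum(bad), 3)
      Bs[[p]][bad, ] <- 0.7 * Bs[[p]][bad, ]
    }
  }

  X <- lapply(setNames(.PARAMS, .PARAMS), comp)
  vec <- function(m) as.vector(t(m))
  ll_groups <- function(Xl) {
    wfpt_loglik_groups_cpp(rt, acc, grp, n_groups,
                           vec(Xl$v), vec(Xl$a), vec(Xl$t0), vec(Xl$z), eps)
  }
  llg <- ll_groups(X)

  # step sizes
  st_As <- matrix(c(0.4, 0.35, 0.11, 0.08), 4, 3, dimnames = list(.PARAMS, NULL))
  st_Bs <- matrix(c(0.13, 0.13, 0.04, 0.03), 4, 1, dimnames = list(.PARAMS, NULL))
  st_A <- matrix(c(0.1, 0.15, 0.04, 0.04), 4, 3, dimnames = list(.PARAMS, NULL))
  st_B <- matrix(c(0.05, 0.08, 0.02, 0.02), 4, 4, dimnames = list(.PARAMS, NULL))
  st_sdA <- matrix(1.0, 4, 3, dimnames = list(.PARAMS, NULL))
  st_sdB <- matrix(1.0, 4, 1, dimnames = list(.PARAMS, NULL))
  st_shA <- matrix(c(0.2, 0.25, 0.06, 0.06), 4, 3, dimnames = list(.PARAMS, NULL))
  st_dlA <- matrix(0.5, 4, 3, dimnames = list(.PARAMS, NULL))
  st_shB <- matrix(c(0.05, 0.08, 0.02, 0.02), 4, 1, dimnames = list(.PARAMS, NULL))
  st_dlB <- matrix(0.5, 4, 1, dimnames = list(.PARAMS, NULL))

  zero2 <- function(m) m * 0
  cnt <- list(as_a = zero2(st_As), as_n = zero2(st_As),
              bs_a = zero2(st_Bs), bs_n = zero2(st_Bs),
              A_a = zero2(st_A), A_n = zero2(st_A),
              B_a = zero2(st_B), B_n = zero2(st_B),
              sdA_a = zero2(st_sdA), sdA_n = zero2(st_sdA),
              sdB_a = zero2(st_sdB), sdB_n = zero2(st_sdB),
              shA_a = zero2(st_shA), shA_n = zero2(st_shA),
              dlA_a = zero2(st_dlA), dlA_n = zero2(st_dlA),
              shB_a = zero2(st_shB), shB_n = zero2(st_shB),
              dlB_a = zero2(st_dlB), dlB_n = zero2(st_dlB))
  fam <- list(subject = c("as", "bs"), mean = c("A", "B", "shA", "shB"),
              sd = c("sdA", "sdB", "dlA", "dlB"))

  n_ret <- cfg$n_iter - cfg$burn_in
  mean_names <- unlist(lapply(.PARAMS, function(p)
    c(paste0(p, "[h", 1:3, "]"), paste0(p, "[bdev", 1:4, "]"))))
  sd_names <- unlist(lapply(.PARAMS, function(p)
    c(paste0("sd_", p, "[h", 1:3, "]"), paste0("sd_", p, "[beta]"))))
  draws <- matrix(NA_real_, n_ret, length(mean_names) + length(sd_names),
                  dimnames = list(NULL, c(mean_names, sd_names)))
  pointwise <- matrix(NA_real_, n_ret, length(rt))
  subj_sum <- lapply(setNames(.PARAMS, .PARAMS), function(p) matrix(0, ns, nc))

  accept_hist <- list()
  win_acc <- 0; win_n <- 0
  cols_h <- lapply(1:3, function(h) which(h_of_cell == h))
  grp_rows <- function(sel_cells) {
    as.vector(t(matrix(seq_len(nc) %in% sel_cells, ns, nc, byrow = TRUE)))
  }

  for (it in seq_len(cfg$n_iter)) {
    ## ---- subject hierarchy baselines: accept per (subject, hierarchy) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      as_old <- As[[p]]
      noise <- matrix(rnorm(ns * 3), ns, 3) *
        matrix(rep(st_As[k, ], each = ns), ns, 3)
      as_new <- as_old + noise
      Asn <- As; Asn[[p]] <- as_new
      Xn <- Asn[[p]][, h_of_cell] + Bs[[p]][, b_of_cell]
      XnL <- X; XnL[[p]] <- Xn
      lln <- ll_groups(XnL)
      dllm <- matrix(lln - llg, ns, nc, byrow = TRUE)
      dll_h <- vapply(1:3, function(h)
        rowSums(dllm[, cols_h[[h]], drop = FALSE]), numeric(ns))
      Amat <- matrix(rep(A[[p]], each = ns), ns, 3)
      sAm <- matrix(rep(sigA[[p]], each = ns), ns, 3)
      dpr <- dnorm(as_new, Amat, sAm, log = TRUE) -
        dnorm(as_old, Amat, sAm, log = TRUE)
      # admissibility of the implied cells, per (s, h) block
      hi <- if (p == "t0") Ut0 else matrix(bu[p], ns, nc)
      okm <- Xn > bl[p] & Xn < hi
      ok_h <- vapply(1:3, function(h)
        rowSums(okm[, cols_h[[h]], drop = FALSE]) == 5, logical(ns))
      ratio <- dll_h + dpr
      accm <- ok_h & matrix(log(runif(ns * 3)), ns, 3) < ratio &
        is.finite(ratio)
      if (any(accm)) {
        As[[p]][accm] <- as_new[accm]
        Xp <- comp(p)
        X[[p]] <- Xp
        sel <- accm[, h_of_cell]                      # ns x nc logical
        gsel <- as.vector(t(sel))
        llg[gsel] <- lln[gsel]
      }
      cnt$as_a[k, ] <- cnt$as_a[k, ] + colSums(accm)
      cnt$as_n[k, ] <- cnt$as_n[k, ] + ns
      win_acc <- win_acc + sum(accm); win_n <- win_n + 3 * ns
    }

    ## ---- subject block offsets: joint zero-sum proposal per subject ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      bs_old <- Bs[[p]]
      d4 <- matrix(rnorm(ns * 4, 0, st_Bs[k, 1]), ns, 4)
      bs_new <- bs_old
      bs_new[, 1:4] <- bs_new[, 1:4] + d4
      bs_new[, 5] <- -rowSums(bs_new[, 1:4])
      Xn <- As[[p]][, h_of_cell] + bs_new[, b_of_cell]
      XnL <- X; XnL[[p]] <- Xn
      lln <- ll_groups(XnL)
      dll_s <- rowSums(matrix(lln - llg, ns, nc, byrow = TRUE))
      # prior lives on the four free offsets; the fifth is determined
      Bmat <- matrix(rep(B[[p]][1:4], each = ns), ns, 4)
      dpr <- rowSums(dnorm(bs_new[, 1:4], Bmat, sigB[[p]], log = TRUE) -
                       dnorm(bs_old[, 1:4], Bmat, sigB[[p]], log = TRUE))
      hi <- if (p == "t0") Ut0 else matrix(bu[p], ns, nc)
      ok <- rowSums(Xn > bl[p] & Xn < hi) == nc
      ratio <- dll_s + dpr
      accs <- ok & log(runif(ns)) < ratio & is.finite(ratio)
      if (any(accs)) {
        Bs[[p]][accs, ] <- bs_new[accs, ]
        X[[p]] <- comp(p)
        gsel <- rep(accs, each = nc)
        llg[gsel] <- lln[gsel]
      }
      cnt$bs_a[k, 1] <- cnt$bs_a[k, 1] + sum(accs)
      cnt$bs_n[k, 1] <- cnt$bs_n[k, 1] + ns
      win_acc <- win_acc + sum(accs); win_n <- win_n + ns
    }

    ## ---- group baselines A (cheap prior-only conditionals) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      prop <- A[[p]] + rnorm(3) * st_A[k, ]
      cm_try <- function(Av) Av[h_of_cell] + B[[p]][b_of_cell]
      ok <- prop > bl[p] & prop < bu[p] &
        vapply(1:3, function(h) {
          sel <- cols_h[[h]]
          all(cm_try(replace(A[[p]], h, prop[h]))[sel] > bl[p] &
                cm_try(replace(A[[p]], h, prop[h]))[sel] < mu_hi[[p]][sel])
        }, TRUE)
      d <- vapply(1:3, function(h) {
        sum(dnorm(As[[p]][, h], prop[h], sigA[[p]][h], log = TRUE) -
              dnorm(As[[p]][, h], A[[p]][h], sigA[[p]][h], log = TRUE))
      }, 0)
      accv <- ok & log(runif(3)) < d & is.finite(d)
      A[[p]][accv] <- prop[accv]
      cnt$A_a[k, ] <- cnt$A_a[k, ] + accv
      cnt$A_n[k, ] <- cnt$A_n[k, ] + 1
      win_acc <- win_acc + sum(accv); win_n <- win_n + 3
    }

    ## ---- group block offsets B (zero-sum, scalar conditionals) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      for (b in 1:4) {
        Bv <- B[[p]]
        d1 <- rnorm(1) * st_B[k, b]
        Bv[b] <- Bv[b] + d1
        Bv[5] <- -sum(Bv[1:4])
        cmv <- A[[p]][h_of_cell] + Bv[b_of_cell]
        ok <- all(abs(Bv) <= half_range[p]) &&
          all(cmv > bl[p] & cmv < mu_hi[[p]])
        if (ok) {
          r <- sum(dnorm(Bs[[p]][, b], Bv[b], sigB[[p]], log = TRUE) -
                     dnorm(Bs[[p]][, b], B[[p]][b], sigB[[p]], log = TRUE))
          if (is.finite(r) && log(runif(1)) < r) {
            B[[p]] <- Bv
            cnt$B_a[k, b] <- cnt$B_a[k, b] + 1
            win_acc <- win_acc + 1
          }
        }
        cnt$B_n[k, b] <- cnt$B_n[k, b] + 1
        win_n <- win_n + 1
      }
    }

    ## ---- scales ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      # baseline scales per hierarchy
      prop <- sigA[[p]] * exp(rnorm(3) * st_sdA[k, ])
      ok <- prop > 0 & prop <= half_range[p]
      d <- vapply(1:3, function(h) {
        sum(dnorm(As[[p]][, h], A[[p]][h], prop[h], log = TRUE) -
              dnorm(As[[p]][, h], A[[p]][h], sigA[[p]][h], log = TRUE))
      }, 0) + (log(prop) - log(sigA[[p]]))
      accv <- ok & log(runif(3)) < d & is.finite(d)
      sigA[[p]][accv] <- prop[accv]
      cnt$sdA_a[k, ] <- cnt$sdA_a[k, ] + accv
      cnt$sdA_n[k, ] <- cnt$sdA_n[k, ] + 1
      win_acc <- win_acc + sum(accv); win_n <- win_n + 3
      # offset scale (one per parameter; free offsets only)
      propB <- sigB[[p]] * exp(rnorm(1) * st_sdB[k, 1])
      if (propB > 0 && propB <= half_range[p]) {
        Bmat <- matrix(rep(B[[p]][1:4], each = ns), ns, 4)
        r <- sum(dnorm(Bs[[p]][, 1:4], Bmat, propB, log = TRUE) -
                   dnorm(Bs[[p]][, 1:4], Bmat, sigB[[p]], log = TRUE)) +
          (log(propB) - log(sigB[[p]]))
        if (is.finite(r) && log(runif(1)) < r) {
          sigB[[p]] <- propB
          cnt$sdB_a[k, 1] <- cnt$sdB_a[k, 1] + 1
          win_acc <- win_acc + 1
        }
      }
      cnt$sdB_n[k, 1] <- cnt$sdB_n[k, 1] + 1
      win_n <- win_n + 1
    }

    ## ---- exact Gibbs scale jumps (plain-normal subject priors) ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      Amat <- matrix(rep(A[[p]], each = ns), ns, 3)
      SSh <- colSums((As[[p]] - Amat)^2)
      propA <- sqrt((SSh / 2) / rgamma(3, shape = (ns - 1) / 2))
      okA <- is.finite(propA) & propA > 0 & propA <= half_range[p]
      sigA[[p]][okA] <- propA[okA]
      Bmat <- matrix(rep(B[[p]][1:4], each = ns), ns, 4)
      SSb <- sum((Bs[[p]][, 1:4] - Bmat)^2)
      propB <- sqrt((SSb / 2) / rgamma(1, shape = (4 * ns - 1) / 2))
      if (is.finite(propB) && propB > 0 && propB <= half_range[p]) {
        sigB[[p]] <- propB
      }
    }

    ## ---- translation: shift a hierarchy baseline and its subjects ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      delta <- rnorm(3) * st_shA[k, ]
      A_new <- A[[p]] + delta
      As_new <- As[[p]] + matrix(rep(delta, each = ns), ns, 3)
      Xn <- As_new[, h_of_cell] + Bs[[p]][, b_of_cell]
      XnL <- X; XnL[[p]] <- Xn
      lln <- ll_groups(XnL)
      dllm <- matrix(lln - llg, ns, nc, byrow = TRUE)
      dll_h <- vapply(1:3, function(h) sum(dllm[, cols_h[[h]], drop = FALSE]), 0)
      hi <- if (p == "t0") Ut0 else matrix(bu[p], ns, nc)
      okm <- Xn > bl[p] & Xn < hi
      cm_new <- A_new[h_of_cell] + B[[p]][b_of_cell]
      ok <- vapply(1:3, function(h) {
        sel <- cols_h[[h]]
        all(okm[, sel]) && all(cm_new[sel] > bl[p] & cm_new[sel] < mu_hi[[p]][sel])
      }, TRUE) & A_new > bl[p] & A_new < bu[p]
      r <- dll_h     # prior deviations unchanged under joint shift
      acch <- ok & log(runif(3)) < r & is.finite(r)
      if (any(acch)) {
        A[[p]][acch] <- A_new[acch]
        As[[p]][, acch] <- As_new[, acch]
        X[[p]] <- comp(p)
        csel <- h_of_cell %in% which(acch)
        gsel <- grp_rows(which(csel))
        llg[gsel] <- lln[gsel]
      }
      cnt$shA_a[k, ] <- cnt$shA_a[k, ] + acch
      cnt$shA_n[k, ] <- cnt$shA_n[k, ] + 1
      win_acc <- win_acc + sum(acch); win_n <- win_n + 3
    }

    ## ---- dilation: scale subject baseline deviations per hierarchy ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      dl <- rnorm(3) * st_dlA[k, ]
      fac <- exp(dl)
      Amat <- matrix(rep(A[[p]], each = ns), ns, 3)
      As_new <- Amat + (As[[p]] - Amat) *
        matrix(rep(fac, each = ns), ns, 3)
      sigA_new <- sigA[[p]] * fac
      Xn <- As_new[, h_of_cell] + Bs[[p]][, b_of_cell]
      XnL <- X; XnL[[p]] <- Xn
      lln <- ll_groups(XnL)
      dllm <- matrix(lln - llg, ns, nc, byrow = TRUE)
      dll_h <- vapply(1:3, function(h) sum(dllm[, cols_h[[h]], drop = FALSE]), 0)
      hi <- if (p == "t0") Ut0 else matrix(bu[p], ns, nc)
      okm <- Xn > bl[p] & Xn < hi
      ok <- vapply(1:3, function(h) all(okm[, cols_h[[h]]]), TRUE) &
        sigA_new > 0 & sigA_new <= half_range[p]
      r <- dll_h + dl   # prior/Jacobian cancel except the scale coordinate
      acch <- ok & log(runif(3)) < r & is.finite(r)
      if (any(acch)) {
        As[[p]][, acch] <- As_new[, acch]
        sigA[[p]][acch] <- sigA_new[acch]
        X[[p]] <- comp(p)
        csel <- h_of_cell %in% which(acch)
        gsel <- grp_rows(which(csel))
        llg[gsel] <- lln[gsel]
      }
      cnt$dlA_a[k, ] <- cnt$dlA_a[k, ] + acch
      cnt$dlA_n[k, ] <- cnt$dlA_n[k, ] + 1
      win_acc <- win_acc + sum(acch); win_n <- win_n + 3
    }

    ## ---- translation: shift a block offset and its subjects jointly ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      delta <- rnorm(4) * st_shB[k, 1]
      Bv <- B[[p]]
      Bv[1:4] <- Bv[1:4] + delta
      Bv[5] <- -sum(Bv[1:4])
      bs_new <- Bs[[p]]
      bs_new[, 1:4] <- bs_new[, 1:4] +
        matrix(rep(delta, each = ns), ns, 4)
      bs_new[, 5] <- -rowSums(bs_new[, 1:4])
      Xn <- As[[p]][, h_of_cell] + bs_new[, b_of_cell]
      XnL <- X; XnL[[p]] <- Xn
      lln <- ll_groups(XnL)
      dll <- sum(lln - llg)
      hi <- if (p == "t0") Ut0 else matrix(bu[p], ns, nc)
      cm_new <- A[[p]][h_of_cell] + Bv[b_of_cell]
      ok <- all(Xn > bl[p] & Xn < hi) &&
        all(abs(Bv) <= half_range[p]) &&
        all(cm_new > bl[p] & cm_new < mu_hi[[p]])
      # prior deviations are unchanged under the joint shift
      if (ok && is.finite(dll) && log(runif(1)) < dll) {
        B[[p]] <- Bv
        Bs[[p]] <- bs_new
        X[[p]] <- comp(p)
        llg <- lln
        cnt$shB_a[k, 1] <- cnt$shB_a[k, 1] + 1
        win_acc <- win_acc + 1
      }
      cnt$shB_n[k, 1] <- cnt$shB_n[k, 1] + 1
      win_n <- win_n + 1
    }

    ## ---- dilation: scale subject offset deviations jointly ----
    for (k in seq_along(.PARAMS)) {
      p <- .PARAMS[k]
      dl <- rnorm(1) * st_dlB[k, 1]
      fac <- exp(dl)
      Bmat <- matrix(rep(B[[p]], each = ns), ns, 5)
      bs_new <- Bmat + (Bs[[p]] - Bmat) * fac
      sigB_new <- sigB[[p]] * fac
      Xn <- As[[p]][, h_of_cell] + bs_new[, b_of_cell]
      XnL <- X; XnL[[p]] <- Xn
      lln <- ll_groups(XnL)
      dll <- sum(lln - llg)
      hi <- if (p == "t0") Ut0 else matrix(bu[p], ns, nc)
      ok <- all(Xn > bl[p] & Xn < hi) && sigB_new > 0 &&
        sigB_new <= half_range[p]
      r <- dll + dl  # free-coordinate Jacobian and prior cancel
      if (ok && is.finite(r) && log(runif(1)) < r) {
        Bs[[p]] <- bs_new
        sigB[[p]] <- sigB_new
        X[[p]] <- comp(p)
        llg <- lln
        cnt$dlB_a[k, 1] <- cnt$dlB_a[k, 1] + 1
        win_acc <- win_acc + 1
      }
      cnt$dlB_n[k, 1] <- cnt$dlB_n[k, 1] + 1
      win_n <- win_n + 1
    }

    ## ---- adaptation & window bookkeeping ----
    if (it %% cfg$adapt_window == 0) {
      phase <- if (it <= cfg$burn_in) "burnin" else "sampling"
      accept_hist[[length(accept_hist) + 1]] <-
        .accept_row(it, phase, win_acc, win_n, cnt, fam)
      if (it < cfg$burn_in) {
        tune <- function(st, a, n) st * exp(ifelse(a / pmax(n, 1) > target, 0.1, -0.1))
        st_As <- tune(st_As, cnt$as_a, cnt$as_n)
        st_Bs <- tune(st_Bs, cnt$bs_a, cnt$bs_n)
        st_A <- tune(st_A, cnt$A_a, cnt$A_n)
        st_B <- tune(st_B, cnt$B_a, cnt$B_n)
        st_sdA <- tune(st_sdA, cnt$sdA_a, cnt$sdA_n)
        st_sdB <- tune(st_sdB, cnt$sdB_a, cnt$sdB_n)
        st_shA <- tune(st_shA, cnt$shA_a, cnt$shA_n)
        st_dlA <- tune(st_dlA, cnt$dlA_a, cnt$dlA_n)
        st_shB <- tune(st_shB, cnt$shB_a, cnt$shB_n)
        st_dlB <- tune(st_dlB, cnt$dlB_a, cnt$dlB_n)
      }
      cnt <- lapply(cnt, function(m) m * 0)
      win_acc <- 0; win_n <- 0
    }

    ## ---- record ----
    if (it > cfg$burn_in) {
      j <- it - cfg$burn_in
      vals <- unlist(lapply(.PARAMS, function(p) c(A[[p]], B[[p]][1:4])),
                     use.names = FALSE)
      sds <- unlist(lapply(.PARAMS, function(p) c(sigA[[p]], sigB[[p]])),
                    use.names = FALSE)
      draws[j, ] <- c(vals, sds)
      vecX <- function(m) as.vector(t(m))
      pointwise[j, ] <- wfpt_loglik_trials_cpp(
        rt, acc, vecX(X$v)[grp], vecX(X$a)[grp], vecX(X$t0)[grp],
        vecX(X$z)[grp], eps)
      for (p in .PARAMS) subj_sum[[p]] <- subj_sum[[p]] + X[[p]]
    }
  }

  list(draws = draws, pointwise = pointwise,
       accept = dplyr::bind_rows(accept_hist), subj_sum = subj_sum)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical DDM fit: model %d (%s), %d subjects, %d trials\n",
    x$spec$model_id, x$spec$label, length(x$subjects), x$n_trials))
  cat(sprintf("  chains: %d x %d (burn-in %d); max R-hat %.4f\n",
              x$config$n_chains, x$config$n_iter, x$config$burn_in,
              x$max_rhat))
  post <- x$acceptance |> dplyr::filter(.data$phase == "sampling")
  if (nrow(post)) {
    cat(sprintf("  post-burn-in acceptance: %.3f\n", mean(post$rate)))
  }
  cat(sprintf("  group-level plug-in log-likelihood: %.2f\n", x$loglik_hat))
  invisible(x)
}
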
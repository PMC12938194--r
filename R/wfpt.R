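# Wiener first-passage-time density and log-likelihood: the likelihood
# engine behind every model.  Computation lives in src/ddm.cpp; these
# wrappers add argument checking and the accuracy-coded trial interface.

#' Wiener first-passage-time density
#'
#' Density of the first-passage time of a drift-diffusion process (drift `v`,
#' boundary separation `a`, non-decision time `t0`, start proportion `z`,
#' unit diffusion coefficient) at the named boundary, evaluated at clock time
#' `t`. Small-time and large-time series representations are selected
#' automatically so the truncation error stays below `eps`. Times at or
#' below `t0` have zero density.
#'
#' @param t Vector of clock times (seconds).
#' @param v,a,t0,z Diffusion parameters (`a > 0.1`, `z` in (0,1), `t0 > 0`).
#' @param boundary `"upper"` or `"lower"`. Upper codes a correct response
#'   throughout the package.
#' @param eps Series truncation tolerance.
#' @return Vector of densities (>= 0).
#' @export
wfpt_density <- function(t, v, a, t0, z, boundary = c("upper", "lower"),
                         eps = 1e-7) {
  boundary <- match.arg(boundary)
  if (!all(is.finite(c(v, a, t0, z))) || a <= 0 || z <= 0 || z >= 1 ||
      t0 < 0 || eps <= 0) {
    rlang::abort("invalid diffusion parameters")
  }
  wfpt_density_cpp(as.numeric(t), v, a, t0, z, boundary == "upper", eps)
}

#' Accuracy-coded log-likelihood of a trial slice
#'
#' Sum of log first-passage densities over trials, with correct responses
#' (`accuracy == 1`) attributed to the upper boundary and errors to the
#' lower. Trials with `rt <= t0` contribute a floor penalty of -700 per
#' trial instead of `-Inf`, so constraint-violating proposals remain
#' rejectable during sampling.
#'
#' @param trials A tibble with columns `rt` (seconds) and `accuracy` (0/1).
#' @param v,a,t0,z Diffusion parameters for the slice.
#' @param eps Series truncation tolerance.
#' @return A single log-likelihood value (0 for an empty slice).
#' @export
ddm_loglik <- function(trials, v, a, t0, z, eps = 1e-7) {
  if (nrow(trials) == 0) return(0)
  stopifnot(all(is.finite(trials$rt)), all(trials$rt > 0))
  n <- nrow(trials)
  sum(wfpt_loglik_trials_cpp(
    trials$rt, as.integer(trials$accuracy),
    rep(v, n), rep(a, n), rep(t0, n), rep(z, n), eps
  ))
}
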
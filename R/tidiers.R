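# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a hierarchical DDM fit
#'
#' One row per group-level parameter: posterior mean, 95% HDI and R-hat.
#'
#' @param x A [fit_ddm()] result.
#' @param mass HDI mass (default 0.95).
#' @param ... Unused.
#' @return A tibble: `term`, `parameter`, `cell`, `kind`, `estimate`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.ddm_fit <- function(x, mass = 0.95, ...) {
  nms <- dimnames(x$draws)[[3]]
  rows <- lapply(nms, function(nm) {
    d <- as.vector(x$draws[, , nm])
    h <- hdi(d, mass)
    tibble::tibble(term = nm, estimate = mean(d),
                   conf.low = h[1], conf.high = h[2])
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(x$rhat, by = c(term = "parameter")) |>
    dplyr::mutate(
      kind = ifelse(startsWith(.data$term, "sd_"), "group_sd", "group_mean"),
      parameter = sub("^(sd_)?([a-z0-9]+)\\[.*$", "\\2", .data$term),
      cell = sub("^.*\\[(.*)\\]$", "\\1", .data$term)
    ) |>
    dplyr::select("term", "parameter", "cell", "kind", "estimate",
                  "conf.low", "conf.high", "rhat")
  out
}

#' Fit-level summary of a hierarchical DDM fit
#'
#' @param x A [fit_ddm()] result.
#' @param ... Unused.
#' @return A one-row tibble: model id, free parameter count, plug-in
#'   log-likelihood, AIC, BIC, max R-hat, mean post-burn-in acceptance,
#'   chain geometry and data size.
#' @export
glance.ddm_fit <- function(x, ...) {
  post <- x$acceptance |> dplyr::filter(.data$phase == "sampling")
  tibble::tibble(
    model_id = x$spec$model_id,
    k = count_free_params(x$spec),
    logLik = x$loglik_hat,
    AIC = ddm_aic(x),
    BIC = ddm_bic(x),
    max_rhat = x$max_rhat,
    acceptance = if (nrow(post)) mean(post$rate) else NA_real_,
    n_chains = x$config$n_chains,
    n_iter = x$config$n_iter,
    n_subjects = length(x$subjects),
    n_trials = x$n_trials
  )
}

#' @rdname tidy.ddm_fit
#' @param type For comparisons: `"models"` (the comparison table) or
#'   `"pairwise"` (pairwise ELPD differences).
#' @export
tidy.ddm_comparison <- function(x, type = c("models", "pairwise"), ...) {
  type <- match.arg(type)
  if (type == "models") x$table else x$pairwise
}

#' @rdname tidy.ddm_fit
#' @export
glance.ddm_comparison <- function(x, ...) {
  tibble::tibble(selected = x$selected,
                 n_models = nrow(x$table),
                 n_significant_pairs = sum(x$pairwise$significant))
}

#' Posterior summaries per design cell
#'
#' @param object A [fit_ddm()] result.
#' @param ... Passed to [tidy.ddm_fit()].
#' @return A ggplot: posterior means with HDI ribbons per parameter.
#' @export
autoplot.ddm_fit <- function(object, ...) {
  td <- tidy(object, ...) |>
    dplyr::filter(.data$kind == "group_mean")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$cell, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "design cell", y = "posterior mean (95% HDI)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ddm_fit
#' @export
autoplot.ddm_comparison <- function(object, ...) {
  td <- object$table
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$model_id))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$elpd_loo,
      ymin = .data$elpd_loo - .data$elpd_se,
      ymax = .data$elpd_loo + .data$elpd_se)) +
    ggplot2::labs(x = "model", y = "ELPD (LOO) +/- SE") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ddm_fit
#' @export
autoplot.dl_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized permutation importance") +
    ggplot2::theme_minimal()
}

#' Learning curves: accuracy and correct RT by block and hierarchy
#'
#' @param trials A trial tibble or [preprocess_trials()] result.
#' @return A ggplot with one panel per dependent variable.
#' @export
plot_learning_curves <- function(trials) {
  if (inherits(trials, "clean_trials")) trials <- trials$trials
  acc <- trials |>
    dplyr::group_by(.data$rule_hierarchy, .data$block) |>
    dplyr::summarise(value = mean(.data$accuracy), .groups = "drop") |>
    dplyr::mutate(dv = "accuracy")
  rts <- trials |>
    dplyr::filter(.data$accuracy == 1) |>
    dplyr::group_by(.data$rule_hierarchy, .data$block) |>
    dplyr::summarise(value = mean(.data$rt), .groups = "drop") |>
    dplyr::mutate(dv = "correct RT (s)")
  ggplot2::ggplot(dplyr::bind_rows(acc, rts),
                  ggplot2::aes(x = .data$block, y = .data$value,
                               colour = factor(.data$rule_hierarchy))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dv), scales = "free_y") +
    ggplot2::labs(colour = "hierarchy", x = "block", y = NULL) +
    ggplot2::theme_minimal()
}
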
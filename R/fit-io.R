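# Posterior persistence and the hierarchy-by-block interaction summary.

#' Persist posterior draws and a fit summary
#'
#' `write_fit_draws` writes the group-level draws in long format
#' (`chain`, `iteration`, `parameter`, `value`); `write_fit_summary`
#' writes a JSON summary (posterior means, 95% HDIs, R-hat, acceptance).
#'
#' @param fit A [fit_ddm()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_draws <- function(fit, path) {
  nms <- dimnames(fit$draws)[[3]]
  long <- do.call(rbind, lapply(seq_len(dim(fit$draws)[2]), function(ch) {
    data.frame(
      chain = ch,
      iteration = rep(seq_len(dim(fit$draws)[1]), length(nms)),
      parameter = rep(nms, each = dim(fit$draws)[1]),
      value = as.vector(fit$draws[, ch, ])
    )
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_draws
#' @export
write_fit_summary <- function(fit, path) {
  td <- tidy(fit)
  post <- fit$acceptance |> dplyr::filter(.data$phase == "sampling")
  out <- list(
    model_id = fit$spec$model_id,
    n_subjects = length(fit$subjects),
    n_trials = fit$n_trials,
    max_rhat = fit$max_rhat,
    acceptance = if (nrow(post)) mean(post$rate) else NA,
    loglik_hat = fit$loglik_hat,
    parameters = td
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Posterior interaction summary for a cell-wise fit
#'
#' Scalar hierarchy-by-block interaction index, computed per posterior
#' draw from the group-level cell means of a cell-wise (Model 4) fit. The
#' default contrast averages the difference-of-differences over adjacent
#' hierarchy pairs and adjacent block pairs:
#' `mean_{h,b} [ (m[h+1,b+1] - m[h,b+1]) - (m[h+1,b] - m[h,b]) ]`.
#' The exact scalar used to summarize an interaction is a modelling
#' choice, so any alternative contrast matrix can be supplied.
#'
#' @param fit A cell-wise [fit_ddm()] result.
#' @param parameter One of `"v"`, `"a"`, `"t0"`, `"z"`.
#' @param contrast Optional 3 x 5 numeric matrix of cell weights replacing
#'   the default difference-of-differences average.
#' @param mass HDI mass (default 0.95).
#' @return A one-row tibble: `parameter`, `estimate` (posterior mean of
#'   the contrast), `conf.low`, `conf.high`.
#' @export
interaction_contrast <- function(fit, parameter = "v", contrast = NULL,
                                 mass = 0.95) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (fit$spec$model_id != 4) {
    rlang::abort("the interaction contrast needs a cell-wise (Model 4) fit")
  }
  if (is.null(contrast)) {
    contrast <- matrix(0, 3, 5)
    npairs <- 2 * 4
    for (h in 1:2) for (b in 1:4) {
      contrast[h + 1, b + 1] <- contrast[h + 1, b + 1] + 1 / npairs
      contrast[h, b + 1] <- contrast[h, b + 1] - 1 / npairs
      contrast[h + 1, b] <- contrast[h + 1, b] - 1 / npairs
      contrast[h, b] <- contrast[h, b] + 1 / npairs
    }
  }
  stopifnot(is.matrix(contrast), all(dim(contrast) == c(3, 5)))
  labs <- outer(1:3, 1:5, function(h, b) paste0(parameter, "[h", h, "b", b, "]"))
  draws <- vapply(seq_len(15), function(i) {
    as.vector(fit$draws[, , labs[i]])
  }, numeric(dim(fit$draws)[1] * dim(fit$draws)[2]))
  m <- draws %*% as.vector(contrast)
  h <- hdi(as.vector(m), mass)
  tibble::tibble(parameter = parameter, estimate = mean(m),
                 conf.low = h[1], conf.high = h[2])
}
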
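# Trial-level feature table for the random-forest stage: experimental
# design columns, cell-mapped diffusion parameters from a hierarchical fit,
# and leakage-free cumulative-moving-average history features.

#' The eleven feature column names
#'
#' Design features (`Block_ID`, `Rule_Hierarchy`, their product), diffusion
#' parameters mapped per participant x cell (`v`, `a`, `t0`, `Z0`, plus the
#' cell convergence index `Rhat`), and dynamic learning features
#' (`Acc_CMA_AllPast`, `RT_CMA_AllPast`, `Rule_alt`). The start proportion
#' `z` is deliberately absent: it is `Z0 / a` and would duplicate
#' information already carried by `Z0` and `a`.
#'
#' @return Character vector of length 11.
#' @export
feature_cols <- function() {
  c("Block_ID", "Rule_Hierarchy", "Block_ID*Rule_Hierarchy",
    "v", "a", "t0", "Z0", "Rhat",
    "Acc_CMA_AllPast", "RT_CMA_AllPast", "Rule_alt")
}

#' Build the trial-level feature table
#'
#' Maps subject-level posterior-mean diffusion parameters (and the
#' group-level cell convergence index) onto each trial by its participant,
#' hierarchy and block; computes the cumulative-moving-average history
#' features strictly from trials `1..t-1` of the same participant (the
#' first trial has no history: accuracy CMA starts at `acc_cma_init`, RT
#' CMA is left `NA` to be imputed from training data at fit time, keeping
#' the leakage guarantee). Targets are trial `Accuracy` and `log_rt`
#' (log seconds; regression models use correct trials only).
#'
#' @param clean A [preprocess_trials()] result (or a trial tibble).
#' @param fit A [fit_ddm()] result supplying per participant x cell
#'   posterior means (the cell-wise Model 4 fit in the full pipeline).
#' @param acc_cma_init First-trial value of the accuracy CMA (default 0.5,
#'   the uninformative prior guess).
#' @param rt_cma_init First-trial value of the RT CMA; `NA` (default)
#'   leaves imputation to the training stage.
#' @return A tibble with the 11 [feature_cols()], the targets `Accuracy`
#'   and `log_rt`, and the keys `participant_id`, `trial_index`.
#' @export
build_features <- function(clean, fit, acc_cma_init = 0.5,
                           rt_cma_init = NA_real_) {
  trials <- if (inherits(clean, "clean_trials")) clean$trials else clean
  stopifnot(inherits(fit, "ddm_fit"))
  trials <- trials |> dplyr::arrange(.data$participant_id, .data$trial_index)

  pars <- fit$subject_means |>
    dplyr::select("participant_id", "parameter", "cell", "estimate") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate") |>
    dplyr::mutate(Z0 = .data$z * .data$a)

  # group-level convergence index per cell: mean R-hat of the four
  # diffusion parameters (falls back to the overall mean when the model's
  # group parameters are not cell-indexed)
  cell_rhat <- vapply(seq_len(fit$spec$n_cells), function(cc) {
    lab <- fit$spec$cells$label[cc]
    nm <- paste0(c("v", "a", "t0", "z"), "[", lab, "]")
    hit <- fit$rhat$rhat[fit$rhat$parameter %in% nm]
    if (length(hit) == 4) mean(hit) else mean(fit$rhat$rhat)
  }, 0)

  cidx <- fit$spec$cell_of(trials$rule_hierarchy, trials$block)
  key <- paste(trials$participant_id, cidx)
  pkey <- paste(pars$participant_id, pars$cell)
  m <- match(key, pkey)
  if (anyNA(m)) rlang::abort("fit does not cover every participant x cell in the data")

  out <- trials |>
    dplyr::mutate(
      Block_ID = .data$block,
      Rule_Hierarchy = .data$rule_hierarchy,
      `Block_ID*Rule_Hierarchy` = .data$block * .data$rule_hierarchy,
      v = pars$v[m], a = pars$a[m], t0 = pars$t0[m], Z0 = pars$Z0[m],
      Rhat = cell_rhat[cidx],
      Rule_alt = .data$rule_switch,
      Accuracy = .data$accuracy,
      log_rt = log(.data$rt)
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      Acc_CMA_AllPast = dplyr::lag(cummean(.data$Accuracy)),
      RT_CMA_AllPast = dplyr::lag(cummean(.data$log_rt))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      Acc_CMA_AllPast = dplyr::coalesce(.data$Acc_CMA_AllPast, acc_cma_init),
      RT_CMA_AllPast = dplyr::coalesce(.data$RT_CMA_AllPast, rt_cma_init)
    )
  out[, c("participant_id", "trial_index", feature_cols(),
          "Accuracy", "log_rt")]
}

#' Write a feature table as CSV with the canonical column names
#'
#' @param features A [build_features()] table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  write.csv(as.data.frame(features, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}
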
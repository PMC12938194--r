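# Preprocessing (participant screening, RT outlier trimming) and the
# 3 x 5 within-subject ANOVA with Greenhouse-Geisser correction.

#' Apply participant screening and RT outlier rules
#'
#' Participant exclusions come first: learning-phase accuracy below
#' `learning_criterion` or a failed hierarchical-response protocol flag.
#' Then RT outliers are trimmed in a single pass: trials faster than
#' `rt_floor` seconds or slower than the participant x hierarchy x block
#' cell mean plus `rt_sd_mult` standard deviations.
#'
#' @param trials A trial tibble.
#' @param exclusions Optional screening tibble (see
#'   [make_exclusion_fixture()]); must cover every participant in `trials`.
#'   `NULL` skips participant screening.
#' @param rt_floor Lower RT bound in seconds (default 0.2).
#' @param rt_sd_mult Upper bound multiplier on the cell SD (default 3).
#' @param learning_criterion Learning-phase accuracy criterion (default 0.8).
#' @return An object of class `clean_trials`: `trials` (retained tibble),
#'   `exclusion_log`, `outlier_log`.
#' @export
preprocess_trials <- function(trials, exclusions = NULL, rt_floor = 0.2,
                              rt_sd_mult = 3, learning_criterion = 0.8) {
  ids <- unique(trials$participant_id)
  if (!is.null(exclusions)) {
    if (!all(ids %in% exclusions$participant_id)) {
      rlang::abort("`exclusions` must cover every participant in `trials`")
    }
    ex <- exclusions |>
      dplyr::mutate(reason = dplyr::case_when(
        .data$hierarchical_response_ok == 0 ~ "protocol",
        .data$learning_accuracy < learning_criterion ~ "learning_accuracy",
        TRUE ~ "none"
      )) |>
      dplyr::select("participant_id", "reason")
  } else {
    ex <- tibble::tibble(participant_id = ids, reason = "none")
  }
  keep_ids <- ex$participant_id[ex$reason == "none"]
  kept <- trials |> dplyr::filter(.data$participant_id %in% keep_ids)

  flagged <- kept |>
    dplyr::group_by(.data$participant_id, .data$rule_hierarchy, .data$block) |>
    dplyr::mutate(
      .hi = mean(.data$rt) + rt_sd_mult * sd(.data$rt),
      bound = dplyr::case_when(
        .data$rt < rt_floor ~ "low",
        is.finite(.data$.hi) & .data$rt > .data$.hi ~ "high",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::ungroup()
  outlier_log <- flagged |>
    dplyr::filter(!is.na(.data$bound)) |>
    dplyr::select("participant_id", "trial_index", "bound")
  clean <- flagged |>
    dplyr::filter(is.na(.data$bound)) |>
    dplyr::select(-".hi", -"bound")

  structure(list(
    trials = clean,
    exclusion_log = ex |> dplyr::filter(.data$participant_id %in% ids),
    outlier_log = outlier_log
  ), class = "clean_trials")
}

#' @export
print.clean_trials <- function(x, ...) {
  n_ex <- sum(x$exclusion_log$reason != "none")
  cat(sprintf(
    "Clean dataset: %d trials from %d participants (%d excluded, %d outlier trials trimmed)\n",
    nrow(x$trials), length(unique(x$trials$participant_id)), n_ex,
    nrow(x$outlier_log)))
  invisible(x)
}

# participant x cell aggregates used by the ANOVA and pairwise stages
.cell_means <- function(trials, dv) {
  if (dv == "accuracy") {
    trials |>
      dplyr::group_by(.data$participant_id, .data$rule_hierarchy, .data$block) |>
      dplyr::summarise(y = mean(.data$accuracy), .groups = "drop")
  } else {
    trials |>
      dplyr::filter(.data$accuracy == 1) |>
      dplyr::group_by(.data$participant_id, .data$rule_hierarchy, .data$block) |>
      dplyr::summarise(y = mean(.data$rt), .groups = "drop")
  }
}

#' Two-way repeated-measures ANOVA on participant cell means
#'
#' Aggregates trials to participant x hierarchy x block means (mean
#' accuracy, or mean correct RT), then runs the 3 x 5 within-subject ANOVA
#' with Greenhouse-Geisser sphericity correction. Effect sizes are partial
#' eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param clean A [preprocess_trials()] result (or a trial tibble).
#' @param dv `"accuracy"` or `"rt"` (mean correct RT, seconds).
#' @param na_action What to do when a participant has an empty cell (e.g.
#'   no correct trial in a hierarchy x block cell for the RT analysis):
#'   `"error"` (default) or `"omit"` the participant with a warning.
#' @return A tibble with one row per effect (`hierarchy`, `block`,
#'   `hierarchy:block`): sums of squares, uncorrected and GG-corrected
#'   degrees of freedom and p-values, F, partial eta squared and GG epsilon.
#' @export
rm_anova <- function(clean, dv = c("accuracy", "rt"),
                     na_action = c("error", "omit")) {
  dv <- match.arg(dv)
  na_action <- match.arg(na_action)
  trials <- if (inherits(clean, "clean_trials")) clean$trials else clean
  cm <- .cell_means(trials, dv)
  full <- cm |> dplyr::count(.data$participant_id) |> dplyr::filter(.data$n == 15L)
  if (nrow(full) < length(unique(cm$participant_id))) {
    if (na_action == "omit") {
      dropped <- setdiff(unique(cm$participant_id), full$participant_id)
      rlang::warn(sprintf("rm_anova: dropping %d participant(s) with empty cells",
                          length(dropped)))
      cm <- cm |> dplyr::filter(.data$participant_id %in% full$participant_id)
    }
  }
  wide <- cm |>
    dplyr::arrange(.data$rule_hierarchy, .data$block) |>
    dplyr::mutate(cell = paste0("h", .data$rule_hierarchy, "b", .data$block)) |>
    dplyr::select("participant_id", "cell", "y") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "y")
  Y <- as.matrix(wide[-1])
  if (anyNA(Y)) rlang::abort("missing participant x cell means (unbalanced data)")
  idata <- expand.grid(block = factor(1:5), hierarchy = factor(1:3))[, 2:1]
  mlm <- stats::lm(Y ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = ~ hierarchy * block,
                   type = 3)
  sm <- summary(av, multivariate = FALSE)
  ut <- sm$univariate.tests
  pa <- sm$pval.adjustments
  effects <- c("hierarchy", "block", "hierarchy:block")
  out <- lapply(effects, function(e) {
    row <- ut[e, ]
    eps <- if (!is.null(pa) && e %in% rownames(pa)) pa[e, "GG eps"] else NA_real_
    pgg <- if (!is.null(pa) && e %in% rownames(pa)) pa[e, "Pr(>F[GG])"] else NA_real_
    if (is.na(eps)) { # sphericity correction unavailable (degenerate data)
      eps <- 1
      pgg <- row[["Pr(>F)"]]
    }
    res <- tibble::tibble(
      effect = e,
      ss = row[["Sum Sq"]],
      ss_error = row[["Error SS"]],
      df1 = row[["num Df"]],
      df2 = row[["den Df"]],
      statistic = row[["F value"]],
      p_uncorrected = row[["Pr(>F)"]],
      gg_epsilon = eps,
      df1_gg = eps * row[["num Df"]],
      df2_gg = eps * row[["den Df"]],
      p_value = pgg,
      pes = row[["Sum Sq"]] / (row[["Sum Sq"]] + row[["Error SS"]])
    )
    if (res$ss < 1e-12 && res$ss_error < 1e-12) {
      # a constant dependent variable carries no effect
      res$statistic <- 0; res$p_uncorrected <- 1; res$p_value <- 1
      res$pes <- 0
    }
    res
  })
  dplyr::bind_rows(out)
}

#' Pairwise paired comparisons on a within-subject factor
#'
#' Participant means per factor level (averaging over the other factor;
#' correct-trial mean RT for `dv = "rt"`), compared by paired t-tests with
#' multiplicity adjustment.
#'
#' @param clean A [preprocess_trials()] result (or a trial tibble).
#' @param dv `"accuracy"` or `"rt"`.
#' @param factor `"hierarchy"` or `"block"`.
#' @param method p-adjustment method (default `"bonferroni"`).
#' @return A tibble: `level_a`, `level_b`, `estimate` (mean a - b), `t`,
#'   `df`, `p_value`, `p_adj`.
#' @export
pairwise_comparisons <- function(clean, dv = c("accuracy", "rt"),
                                 factor = c("hierarchy", "block"),
                                 method = "bonferroni") {
  dv <- match.arg(dv)
  factor <- match.arg(factor)
  trials <- if (inherits(clean, "clean_trials")) clean$trials else clean
  cm <- .cell_means(trials, dv)
  fcol <- if (factor == "hierarchy") "rule_hierarchy" else "block"
  lev <- cm |>
    dplyr::group_by(.data$participant_id, level = .data[[fcol]]) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "level", values_from = "y")
  mat <- as.matrix(lev[-1])
  levels_ <- as.integer(colnames(mat))
  combs <- utils::combn(seq_along(levels_), 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    tt <- stats::t.test(mat[, a], mat[, b], paired = TRUE)
    tibble::tibble(
      level_a = levels_[a], level_b = levels_[b],
      estimate = unname(tt$estimate),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p_value, method = method)
  out
}
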
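# End-to-end orchestration: simulate -> preprocess -> ANOVA -> fit x 4 ->
# compare -> PPC -> features -> forests -> importance -> Top-k report.
# Deterministic given the configuration; every artifact file carries the
# configuration hash in its name.

#' Pipeline configuration
#'
#' The `"desk"` preset keeps a full run tractable on one core (10
#' participants, 3 x 1500 iterations, 150 trees, 10 importance repeats);
#' `"full"` mirrors the reference study conditions (40 collected
#' participants screened to 34, 3 x 3000 iterations, 300 trees, 50
#' repeats).
#'
#' @param preset `"desk"` or `"full"`.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param ... Overrides for any configuration entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("desk", "full"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(n_collected = 10L, screen = FALSE, trials_per_cell = 6L,
         n_iter = 1500L, burn_in = 750L, n_trees = 150L, repeats = 10L)
  } else {
    list(n_collected = 40L, screen = TRUE, trials_per_cell = 6L,
         n_iter = 3000L, burn_in = 1500L, n_trees = 300L, repeats = 50L)
  }
  cfg <- utils::modifyList(
    c(base, list(preset = preset, seed = as.integer(seed), n_chains = 3L,
                 adapt_window = 200L, target_accept = 0.30,
                 dt = 0.001, cap = 60, topk = 8L, kfold = 5L)),
    list(...)
  )
  .validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.validate_pipeline_config <- function(cfg) {
  need <- c("seed", "n_collected", "trials_per_cell", "n_iter", "burn_in",
            "n_chains", "n_trees", "repeats", "topk", "kfold")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    rlang::abort(paste("pipeline config is missing:",
                       paste(missing, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    rlang::abort("pipeline config needs a single integer `seed`")
  }
  if (cfg$burn_in >= cfg$n_iter) rlang::abort("burn_in must be < n_iter")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may contain any [pipeline_config()] entry; `preset` and `seed`
#' default to `"desk"` and 1. Validation runs before anything is computed.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    rlang::abort("config must be a .yaml/.yml or .json file")
  }
  preset <- if (is.null(raw$preset)) "desk" else raw$preset
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  raw$preset <- NULL; raw$seed <- NULL
  do.call(pipeline_config, c(list(preset = preset, seed = seed), raw))
}

# short deterministic hash of the configuration, stamped into file names
.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","), ""),
             sep = "=", collapse = ";")
  raw <- utils::head(charToRaw(s), 10000)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic dataset drawn under the
#' configuration: design + population simulation, participant screening
#' and RT trimming, both ANOVAs, the four hierarchical model fits, model
#' comparison, a posterior predictive check of the selected model, the
#' feature table and both forests with permutation importance and the
#' Top-k comparison. Re-running with the same configuration reproduces
#' every output.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (`NULL` = no files written).
#' @param models Which model ids to fit (default 1:4).
#' @return A list of class `pipeline_result` with every stage's output.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         models = 1:4) {
  .validate_pipeline_config(config)
  hash <- .config_hash(config)
  say <- function(...) message(sprintf("[driftlearn %s] ", hash), sprintf(...))
  emit <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, sprintf("%s_%s.csv", name, hash))
    write.csv(as.data.frame(obj, check.names = FALSE), path, row.names = FALSE)
    invisible(path)
  }
  seeds <- config$seed + 1:10 * 1000L

  say("simulating %d participants", config$n_collected)
  pop <- ddm_population("cell")
  design <- generate_design(config$n_collected, config$trials_per_cell,
                            seed = seeds[1])
  params <- draw_subject_params(pop, config$n_collected, seed = seeds[2])
  trials <- simulate_trials(design, params, dt = config$dt, seed = seeds[3],
                            cap = config$cap)
  emit(trials, "trials")

  excl <- if (isTRUE(config$screen)) {
    make_exclusion_fixture(seed = seeds[4], n = config$n_collected)
  } else NULL
  clean <- preprocess_trials(trials, excl)
  say("retained %d participants, %d trials",
      length(unique(clean$trials$participant_id)), nrow(clean$trials))
  emit(clean$trials, "clean_trials")

  anova_acc <- rm_anova(clean, "accuracy", na_action = "omit")
  anova_rt <- rm_anova(clean, "rt", na_action = "omit")
  emit(dplyr::bind_rows(dplyr::mutate(anova_acc, dv = "accuracy"),
                        dplyr::mutate(anova_rt, dv = "rt")), "anova")

  fits <- list()
  for (m in models) {
    say("fitting model %d", m)
    fits[[as.character(m)]] <- fit_ddm(
      clean$trials, m,
      mcmc_config(config$n_chains, config$n_iter, config$burn_in,
                  config$adapt_window, config$target_accept,
                  seed = seeds[5] + m)
    )
  }
  comparison <- if (length(fits) > 1) compare_models(unname(fits)) else NULL
  if (!is.null(comparison)) {
    emit(comparison$table, "comparison")
    say("selected model %d", comparison$selected)
  }
  best_id <- if (!is.null(comparison)) as.character(comparison$selected) else
    names(fits)[1]
  best <- fits[[best_id]]
  ppc <- posterior_predictive_check(best, seed = seeds[6])

  say("building features and forests")
  feats <- build_features(clean, best)
  emit(feats, "features")
  fc_cls <- forest_config("classification", config$n_trees, seed = seeds[7])
  cls <- train_forest(feats, feats$Accuracy, fc_cls)
  imp_cls <- permutation_importance(cls, feats, feats$Accuracy,
                                    repeats = config$repeats, seed = seeds[8])
  emit(imp_cls, "importance_classification")

  ok <- feats$Accuracy == 1
  fc_reg <- forest_config("regression", config$n_trees, seed = seeds[7] + 1)
  reg <- train_forest(feats[ok, ], feats$log_rt[ok], fc_reg)
  imp_reg <- permutation_importance(reg, feats[ok, ], feats$log_rt[ok],
                                    repeats = config$repeats,
                                    seed = seeds[8] + 1)
  emit(imp_reg, "importance_regression")

  topk <- topk_refit(feats, feats$Accuracy, imp_cls, k = config$topk,
                     config = fc_cls, groups = feats$participant_id,
                     K = config$kfold, seed = seeds[9])
  emit(topk, "topk_comparison")

  structure(list(
    config = config, hash = hash, trials = trials, clean = clean,
    anova = list(accuracy = anova_acc, rt = anova_rt),
    fits = fits, comparison = comparison, ppc = ppc,
    features = feats,
    forests = list(classification = cls, regression = reg),
    importance = list(classification = imp_cls, regression = imp_reg),
    topk = topk
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("driftlearn pipeline run", x$hash, "\n")
  if (!is.null(x$comparison)) {
    cat("  selected model:", x$comparison$selected, "\n")
  }
  cat(sprintf("  PPC max RT-quantile gap: %.3f s\n", x$ppc$max_rt_discrepancy))
  cat("  top classification features:",
      paste(utils::head(x$importance$classification$feature, 3), collapse = ", "),
      "\n")
  invisible(x)
}
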
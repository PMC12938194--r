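# The four-model space: which experimental factor(s) each diffusion
# parameter's group-level location varies over.  All four parameters share
# the same factor map within a model.

#' Define one of the four competing model structures
#'
#' * Model 1 - hierarchy-only: one group mean per rule hierarchy (3 cells).
#' * Model 2 - block-only: one group mean per block (5 cells).
#' * Model 3 - additive: hierarchy baselines plus zero-sum block offsets.
#' * Model 4 - cell-wise: a free group mean per hierarchy x block cell (15).
#'
#' Group-level standard deviations are pooled over blocks (one per parameter
#' and hierarchy for Models 1/3/4, one per parameter and block for Model 2):
#' with only a handful of trials per design cell, a free scale per cell is
#' not identifiable.
#'
#' @param model_id Integer 1-4.
#' @return An object of class `ddm_model_spec`.
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% 1:4) rlang::abort("`model_id` must be 1, 2, 3 or 4")
  id <- as.integer(model_id)
  if (id == 1L) {
    cells <- tibble::tibble(cell = 1:3, rule_hierarchy = 1:3,
                            block = NA_integer_, label = paste0("h", 1:3))
    cell_of <- function(h, b) h
    sd_group <- cells$rule_hierarchy
    label <- "hierarchy-only"
  } else if (id == 2L) {
    cells <- tibble::tibble(cell = 1:5, rule_hierarchy = NA_integer_,
                            block = 1:5, label = paste0("b", 1:5))
    cell_of <- function(h, b) b
    sd_group <- cells$block
    label <- "block-only"
  } else {
    grid <- tidyr::crossing(rule_hierarchy = 1:3, block = 1:5)
    cells <- tibble::tibble(
      cell = seq_len(15L),
      rule_hierarchy = grid$rule_hierarchy,
      block = grid$block,
      label = paste0("h", grid$rule_hierarchy, "b", grid$block)
    )
    cell_of <- function(h, b) (h - 1L) * 5L + b
    sd_group <- cells$rule_hierarchy
    label <- if (id == 3L) "additive" else "cell-wise"
  }
  structure(
    list(
      model_id = id,
      label = label,
      additive = id == 3L,
      n_cells = nrow(cells),
      cells = cells,
      cell_of = cell_of,
      sd_group = sd_group,           # sd-pool index per cell
      n_sd_groups = length(unique(sd_group))
    ),
    class = "ddm_model_spec"
  )
}

#' Free group-level location parameters implied by a model structure
#'
#' Four diffusion parameters times the number of distinct group means the
#' factor map induces: 12 (Model 1), 20 (Model 2), 28 (Model 3: 3 hierarchy
#' baselines + 4 free zero-sum block offsets per parameter), 60 (Model 4).
#'
#' @param spec A `ddm_model_spec` (or a model id 1-4).
#' @return Integer count of free group-level location parameters.
#' @export
count_free_params <- function(spec) {
  if (is.numeric(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "ddm_model_spec"))
  per_par <- switch(spec$model_id, 3L, 5L, 7L, 15L)
  4L * per_par
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat(sprintf("DDM model %d (%s): %d group cells, %d free location parameters\n",
              x$model_id, x$label, x$n_cells, count_free_params(x)))
  invisible(x)
}
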
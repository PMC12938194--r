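# Synthetic task designs, ground-truth parameter populations and the
# participant-exclusion fixture.  The defaults mirror the study conditions:
# 5 blocks x 3 rule hierarchies x 6 trials per cell (90 trials/participant),
# 40 collected participants of whom 6 fail the screening rules.

#' Admissible ranges for the four diffusion parameters
#'
#' The constraint region used throughout: boundary separation `a > 0.1`,
#' start proportion `z` strictly inside (0, 1), non-decision time `t0`
#' positive, drift `v` bounded for the uniform hyperprior. Non-decision time
#' is measured in seconds.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
ddm_param_bounds <- function() {
  tibble::tibble(
    parameter = c("v", "a", "t0", "z"),
    lower = c(-5, 0.1, 0.01, 0.01),
    upper = c(5, 10, 3, 0.99)
  )
}

# Hierarchy-level and block-level posterior-mean defaults for the generating
# population.  Non-decision times are stored in seconds.
.hierarchy_means <- function() {
  tibble::tibble(
    parameter = rep(c("v", "a", "t0", "z"), each = 3L),
    rule_hierarchy = rep(1:3, 4L),
    mean = c(
      0.92, 0.60, 0.38,          # drift rate v
      2.98, 5.17, 6.36,          # boundary separation a
      0.7312, 0.9584, 0.9506,    # non-decision time t0 (s)
      0.29, 0.18, 0.23           # start proportion z
    )
  )
}

.block_means <- function() {
  tibble::tibble(
    parameter = rep(c("v", "a", "t0", "z"), each = 5L),
    block = rep(1:5, 4L),
    mean = c(
      0.48, 0.58, 0.62, 0.76, 0.72,
      5.08, 4.85, 4.71, 4.93, 4.61,
      0.9355, 0.9407, 0.9089, 0.7668, 0.8483,
      0.26, 0.23, 0.24, 0.20, 0.23
    )
  )
}

# Default between-subject standard deviations, chosen once at scales typical
# of individual differences reported for hierarchical diffusion fits.
.default_sds <- c(v = 0.10, a = 0.20, t0 = 0.05, z = 0.03)

#' Generating population for synthetic diffusion data
#'
#' Returns group-level means and between-subject standard deviations for the
#' four diffusion parameters, keyed by the experimental factor(s) they vary
#' over. Defaults are the hierarchy-level (or block-level) posterior means of
#' the reference fit; cell-level populations combine the two additively
#' (hierarchy mean plus block deviation from the block average), clipped to
#' the admissible region.
#'
#' @param level One of `"hierarchy"`, `"block"`, `"cell"`: which factor(s)
#'   the generating parameters vary over.
#' @param sds Named numeric vector of between-subject standard deviations for
#'   `v`, `a`, `t0`, `z`. Use zeros for a homogeneous population.
#' @return A tibble with columns `parameter`, `rule_hierarchy`, `block`
#'   (either may be `NA` when the parameter does not vary over that factor),
#'   `mean`, `sd`.
#' @export
ddm_population <- function(level = c("hierarchy", "block", "cell"),
                           sds = .default_sds) {
  level <- match.arg(level)
  stopifnot(all(c("v", "a", "t0", "z") %in% names(sds)), all(sds >= 0))
  if (level == "hierarchy") {
    out <- .hierarchy_means() |> dplyr::mutate(block = NA_integer_)
  } else if (level == "block") {
    out <- .block_means() |> dplyr::mutate(rule_hierarchy = NA_integer_)
  } else {
    h <- .hierarchy_means()
    b <- .block_means() |>
      dplyr::group_by(.data$parameter) |>
      dplyr::mutate(dev = .data$mean - mean(.data$mean)) |>
      dplyr::ungroup() |>
      dplyr::select("parameter", "block", "dev")
    out <- tidyr::crossing(h, block = 1:5) |>
      dplyr::left_join(b, by = c("parameter", "block")) |>
      dplyr::mutate(mean = .data$mean + .data$dev) |>
      dplyr::select(-"dev")
    bounds <- ddm_param_bounds()
    out <- out |>
      dplyr::left_join(bounds, by = "parameter") |>
      dplyr::mutate(mean = pmin(pmax(.data$mean, .data$lower + 0.05),
                                .data$upper - 0.05)) |>
      dplyr::select(-"lower", -"upper")
  }
  out |>
    dplyr::mutate(sd = unname(sds[.data$parameter])) |>
    dplyr::select("parameter", "rule_hierarchy", "block", "mean", "sd") |>
    .check_population()
}

.check_population <- function(pop) {
  bounds <- ddm_param_bounds()
  chk <- dplyr::left_join(pop, bounds, by = "parameter")
  bad <- chk$mean <= chk$lower | chk$mean >= chk$upper
  if (any(bad)) {
    rlang::abort(paste0(
      "population means outside the admissible region for: ",
      paste(unique(chk$parameter[bad]), collapse = ", ")
    ))
  }
  if (any(pop$sd < 0)) rlang::abort("population sds must be non-negative")
  pop
}

#' Generate a randomized trial design
#'
#' Builds the chronological trial list for each participant: 5 blocks, each
#' containing `trials_per_cell` trials of every rule hierarchy (1-3) in a
#' randomized order. With the default `trials_per_cell = 6` each participant
#' performs 90 trials, 18 per block and 30 per hierarchy. The `rule_switch`
#' flag is 1 when the hierarchy differs from the preceding trial (0 for each
#' participant's first trial).
#'
#' @param n_participants Number of participants (>= 1).
#' @param trials_per_cell Trials per block x hierarchy cell (>= 1).
#' @param seed Optional integer seed for the within-block shuffles.
#' @param n_blocks,n_hierarchies Design size; fixed at 5 and 3 by default.
#' @return A tibble with columns `participant_id`, `block`,
#'   `rule_hierarchy`, `trial_index`, `rule_switch`.
#' @export
generate_design <- function(n_participants, trials_per_cell = 6L, seed = NULL,
                            n_blocks = 5L, n_hierarchies = 3L) {
  if (!is.numeric(n_participants) || n_participants < 1 ||
      n_participants != round(n_participants)) {
    rlang::abort("`n_participants` must be a positive integer")
  }
  if (!is.numeric(trials_per_cell) || trials_per_cell < 1 ||
      trials_per_cell != round(trials_per_cell)) {
    rlang::abort("`trials_per_cell` must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  per_block <- rep(seq_len(n_hierarchies), each = trials_per_cell)
  rows <- lapply(seq_len(n_participants), function(p) {
    hier <- unlist(lapply(seq_len(n_blocks), function(b) sample(per_block)))
    tibble::tibble(
      participant_id = as.integer(p),
      block = rep(seq_len(n_blocks), each = length(per_block)),
      rule_hierarchy = as.integer(hier),
      trial_index = seq_along(hier)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(rule_switch = as.integer(
      .data$rule_hierarchy != dplyr::lag(.data$rule_hierarchy,
                                         default = dplyr::first(.data$rule_hierarchy))
    )) |>
    dplyr::ungroup()
}

# inverse-CDF sampling from a truncated normal; exact and vectorized
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- numeric(n)
  degen <- sd == 0
  out[degen] <- mean[degen]
  if (any(!degen)) {
    i <- !degen
    lo <- pnorm(lower, mean[i], sd[i])
    hi <- pnorm(upper, mean[i], sd[i])
    u <- runif(sum(i), lo, hi)
    out[i] <- qnorm(u, mean[i], sd[i])
    # guard against numerically exact bounds
    out[i] <- pmin(pmax(out[i], lower + 1e-9), upper - 1e-9)
  }
  out
}

#' Draw subject-level diffusion parameters around a generating population
#'
#' Subject values are drawn from normal distributions centred on the group
#' means with the group standard deviations, truncated to the admissible
#' region (`a > 0.1`, `z` in (0,1), `t0 > 0`). With all sds equal to zero the
#' subject values equal the group means exactly.
#'
#' @param pop A population tibble from [ddm_population()] (or same shape).
#' @param n_participants Number of subjects to draw.
#' @param seed Optional integer seed.
#' @return A tibble with columns `participant_id`, `parameter`,
#'   `rule_hierarchy`, `block`, `value`.
#' @export
draw_subject_params <- function(pop, n_participants, seed = NULL) {
  .check_population(pop)
  if (!is.null(seed)) set.seed(seed)
  bounds <- ddm_param_bounds()
  pop2 <- dplyr::left_join(pop, bounds, by = "parameter")
  rows <- lapply(seq_len(nrow(pop2)), function(i) {
    val <- .rtruncnorm(n_participants, pop2$mean[i], pop2$sd[i],
                       pop2$lower[i], pop2$upper[i])
    tibble::tibble(
      participant_id = seq_len(n_participants),
      parameter = pop2$parameter[i],
      rule_hierarchy = pop2$rule_hierarchy[i],
      block = pop2$block[i],
      value = val
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$participant_id)
}

# Resolve per-trial parameter values from a subject-parameter table whose
# rows are keyed by participant and whichever factor(s) the parameter varies
# over (NA = does not vary).
.trial_params <- function(design, params) {
  wide <- params |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")
  by_cell <- !all(is.na(wide$rule_hierarchy)) & !all(is.na(wide$block))
  if (by_cell) {
    out <- dplyr::left_join(
      design, wide,
      by = c("participant_id", "rule_hierarchy", "block")
    )
  } else if (!all(is.na(wide$rule_hierarchy))) {
    out <- dplyr::left_join(
      design, dplyr::select(wide, -"block"),
      by = c("participant_id", "rule_hierarchy")
    )
  } else {
    out <- dplyr::left_join(
      design, dplyr::select(wide, -"rule_hierarchy"),
      by = c("participant_id", "block")
    )
  }
  if (anyNA(out$v) || anyNA(out$a) || anyNA(out$t0) || anyNA(out$z)) {
    rlang::abort("missing cell parameters for some design cells")
  }
  out
}

#' Simulate choice/RT data by forward diffusion
#'
#' Runs an Euler-Maruyama simulation of the diffusion process (unit diffusion
#' coefficient) for every trial of `design`, using the subject-level
#' parameters in `params`. The upper boundary codes a correct response; the
#' start point sits at proportion `z` of the boundary separation. Reaction
#' time is the non-decision time plus the first-passage time; trials that
#' fail to terminate within `cap` seconds are resampled.
#'
#' @param design A design tibble from [generate_design()].
#' @param params A subject-parameter tibble from [draw_subject_params()].
#' @param dt Simulation step in seconds (default 0.001).
#' @param seed Optional integer seed.
#' @param cap Hard cap on the decision time, seconds (default 60, chosen so
#'   the resampled mass is negligible even for the slowest admissible cells).
#' @return The design tibble with added columns `rt` (seconds) and
#'   `accuracy` (0/1).
#' @export
simulate_trials <- function(design, params, dt = 0.001, seed = NULL,
                            cap = 60) {
  stopifnot(dt > 0, cap > dt)
  force(design); force(params)   # evaluate before touching the RNG state
  if (!is.null(seed)) set.seed(seed)
  tp <- .trial_params(design, params)
  key <- paste(tp$participant_id, tp$rule_hierarchy, tp$block)
  tp$rt <- NA_real_
  tp$accuracy <- NA_integer_
  for (k in unique(key)) {
    idx <- which(key == k)
    sim <- simulate_fpt_cpp(length(idx), tp$v[idx][1], tp$a[idx][1],
                            tp$z[idx][1], dt, cap)
    tp$rt[idx] <- tp$t0[idx][1] + sim$t_dec
    tp$accuracy[idx] <- sim$upper
  }
  tp |> dplyr::select(-"v", -"a", -"t0", -"z")
}

#' Analytic probability of absorption at the upper boundary
#'
#' Closed-form probability that a diffusion with drift `v`, boundary
#' separation `a` and start proportion `z` (unit diffusion coefficient) is
#' absorbed at the upper boundary: `(1 - exp(-2vaz)) / (1 - exp(-2va))`,
#' continuously extended to `z` at `v = 0`.
#'
#' @param v,a,z Diffusion parameters (vectorized).
#' @return Absorption probability in `[0, 1]`.
#' @export
absorption_prob <- function(v, a, z) {
  out <- ifelse(
    abs(v) < 1e-12, z,
    (1 - exp(-2 * v * a * z)) / (1 - exp(-2 * v * a))
  )
  pmin(pmax(out, 0), 1)
}

#' Participant screening fixture
#'
#' Emulates the study's data-collation stage: `n` collected participants of
#' whom exactly `n_low_acc` failed to reach the 80% learning-phase accuracy
#' criterion and exactly `n_protocol` failed to make hierarchical responses
#' as required (disjoint sets). Defaults reproduce the reported composition:
#' 40 collected, 6 excluded (15%), 34 retained.
#'
#' @param seed Optional integer seed.
#' @param n,n_low_acc,n_protocol Fixture composition.
#' @return A tibble with columns `participant_id`, `learning_accuracy`,
#'   `hierarchical_response_ok`.
#' @export
make_exclusion_fixture <- function(seed = NULL, n = 40L, n_low_acc = 5L,
                                   n_protocol = 1L) {
  stopifnot(n_low_acc + n_protocol <= n)
  if (!is.null(seed)) set.seed(seed)
  flagged <- sample(n, n_low_acc + n_protocol)
  low <- flagged[seq_len(n_low_acc)]
  proto <- flagged[-seq_len(n_low_acc)]
  acc <- runif(n, 0.82, 0.99)
  acc[low] <- runif(n_low_acc, 0.50, 0.79)
  tibble::tibble(
    participant_id = seq_len(n),
    learning_accuracy = acc,
    hierarchical_response_ok = as.integer(!seq_len(n) %in% proto)
  )
}

#' Write / read a trial table as CSV
#'
#' The on-disk format has the header
#' `participant_id,block,rule_hierarchy,trial_index,rule_switch,rt,accuracy`
#' with RT in seconds at 6 decimal places.
#'
#' @param trials A trial tibble with the columns above.
#' @param path File path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns the trial tibble.
#' @export
write_trial_csv <- function(trials, path) {
  cols <- c("participant_id", "block", "rule_hierarchy", "trial_index",
            "rule_switch", "rt", "accuracy")
  stopifnot(all(cols %in% names(trials)))
  out <- trials[cols]
  out$rt <- sprintf("%.6f", out$rt)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  tibble::as_tibble(read.csv(path)) |>
    dplyr::mutate(rt = as.numeric(.data$rt))
}
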
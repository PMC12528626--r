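#' Quantile-based coarsening of a matching covariate
#'
#' Cuts a numeric covariate into `k` near-equal-count bins at empirical
#' quantiles (half-open, right-closed intervals). Missing values map to a
#' dedicated `"missing"` bin at every coarsening level, so e.g. absent PSA
#' is matched exactly on its absence. With fewer than `k` distinct values
#' the spec degenerates to fewer bins (a warning is raised when a single
#' bin remains).
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param k Requested number of bins (>= 1).
#' @param variable Name recorded in the spec (for reporting).
#' @return A `bin_spec`: list with `variable`, `k_requested`, `k_effective`,
#'   `breaks` (interior cut points, strictly increasing) and `missing_bin`.
#' @export
#' @examples
#' compute_bins(1:9, k = 3)
compute_bins <- function(values, k, variable = "x") {
  if (k < 1) rlang::abort("k must be >= 1", class = "mricdr_config_error")
  nonmiss <- values[!is.na(values)]
  breaks <- numeric(0)
  if (length(nonmiss) > 0 && k > 1) {
    qs <- stats::quantile(nonmiss, probs = seq_len(k - 1) / k, type = 7,
                          names = FALSE)
    breaks <- unique(qs)
    # a break at the maximum would leave an empty last bin; drop it
    breaks <- breaks[breaks < max(nonmiss)]
  }
  k_eff <- length(breaks) + 1L
  if (k > 1 && k_eff == 1L) {
    rlang::warn(sprintf(
      "covariate '%s' has too few distinct values; a single bin is used",
      variable
    ))
  }
  structure(
    list(
      variable = variable,
      k_requested = as.integer(k),
      k_effective = k_eff,
      breaks = breaks,
      missing_bin = anyNA(values)
    ),
    class = "bin_spec"
  )
}

#' Assign values to the bins of a `bin_spec`
#'
#' @param values Numeric vector.
#' @param spec A [compute_bins()] result.
#' @return Character vector of bin labels (`"b1"`, `"b2"`, ..., `"missing"`).
#' @export
assign_bins <- function(values, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  idx <- findInterval(values, spec$breaks, left.open = TRUE) + 1L
  lab <- paste0("b", idx)
  lab[is.na(values)] <- "missing"
  lab
}

# composite exact-match keys at one coarsening tier
match_keys <- function(exams, age_spec, psa_spec) {
  paste(exams$facility, exams$biopsy_status,
        assign_bins(exams$age, age_spec),
        assign_bins(exams$psa, psa_spec),
        sep = "|")
}

#' One matching round: one control per target, narrow bins preferred
#'
#' Targets are visited in random order. For each target the candidates are
#' the still-available pool members equal on facility, biopsy status and the
#' narrow (6-bin) age/PSA coarsening; when none remain, the wide (3-bin)
#' coarsening is tried. One candidate is chosen uniformly at random and
#' removed from the round's pool. If any target has no candidate at either
#' tier the whole round fails and consumes no controls.
#'
#' @param targets,pool Examination tibbles (disjoint).
#' @param specs List with elements `age_narrow`, `age_wide`, `psa_narrow`,
#'   `psa_wide` (from [compute_bins()]); computed on the union by
#'   [repeated_matching()].
#' @return On success a tibble `target_id`, `control_id`, `tier`; on failure
#'   `NULL`.
#' @export
match_round <- function(targets, pool, specs) {
  if (nrow(targets) == 0) {
    rlang::abort("targets must be non-empty", class = "mricdr_precondition_error")
  }
  t_narrow <- match_keys(targets, specs$age_narrow, specs$psa_narrow)
  t_wide <- match_keys(targets, specs$age_wide, specs$psa_wide)
  p_narrow <- match_keys(pool, specs$age_narrow, specs$psa_narrow)
  p_wide <- match_keys(pool, specs$age_wide, specs$psa_wide)

  avail <- rep(TRUE, nrow(pool))
  order_idx <- sample.int(nrow(targets))
  chosen <- integer(nrow(targets))
  tier <- character(nrow(targets))
  for (i in order_idx) {
    cand <- which(avail & p_narrow == t_narrow[i])
    this_tier <- "narrow"
    if (length(cand) == 0) {
      cand <- which(avail & p_wide == t_wide[i])
      this_tier <- "wide"
    }
    if (length(cand) == 0) return(NULL)
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    avail[pick] <- FALSE
    chosen[i] <- pick
    tier[i] <- this_tier
  }
  tibble::tibble(
    target_id = targets$exam_id,
    control_id = pool$exam_id[chosen],
    tier = tier
  )
}

#' Repeated coarsened exact matching
#'
#' Runs 1:1 matching rounds iteratively: every completed round pairs each
#' target with one unused control (exact on facility and biopsy status,
#' coarsened-exact on age and PSA with a narrow-to-wide fallback); matched
#' controls are removed from the pool so no control is reused. A round that
#' cannot match every target is retried with fresh random visiting orders up
#' to `round_attempts` times, then matching stops. The final control:target
#' ratio equals the number of completed rounds.
#'
#' @param targets,pool Examination tibbles with `exam_id`, `age`, `psa`,
#'   `facility`, `biopsy_status`; disjoint exam ids.
#' @param max_rounds Maximum number of rounds (default 20).
#' @param round_attempts Random-order retries before declaring a round
#'   infeasible (default 10).
#' @param seed Integer seed; fixed seed gives identical matches.
#' @param k_narrow,k_wide Bin counts of the two coarsening tiers (defaults
#'   6 and 3). Quantiles are computed once on the union of targets and pool.
#' @return A `matched_cohort` object; see [tidy.matched_cohort()] and
#'   [glance.matched_cohort()].
#' @export
repeated_matching <- function(targets, pool, max_rounds = 20,
                              round_attempts = 10, seed = 1,
                              k_narrow = 6, k_wide = 3) {
  targets <- tibble::as_tibble(targets)
  pool <- tibble::as_tibble(pool)
  if (length(intersect(targets$exam_id, pool$exam_id)) > 0) {
    rlang::abort("targets and pool must be disjoint",
                 class = "mricdr_precondition_error")
  }
  empty <- tibble::tibble(
    target_id = character(), control_id = character(),
    round = integer(), tier = character()
  )
  if (nrow(targets) == 0 || nrow(pool) == 0) {
    return(new_matched_cohort(empty, targets$exam_id, 0L))
  }
  withr::local_seed(seed)
  all_vals <- dplyr::bind_rows(
    dplyr::select(targets, "age", "psa"),
    dplyr::select(pool, "age", "psa")
  )
  specs <- list(
    age_narrow = compute_bins(all_vals$age, k_narrow, "age"),
    age_wide = compute_bins(all_vals$age, k_wide, "age"),
    psa_narrow = compute_bins(all_vals$psa, k_narrow, "psa"),
    psa_wide = compute_bins(all_vals$psa, k_wide, "psa")
  )
  matches <- empty
  pool_left <- pool
  rounds <- 0L
  while (rounds < max_rounds && nrow(pool_left) >= nrow(targets)) {
    res <- NULL
    for (a in seq_len(round_attempts)) {
      res <- match_round(targets, pool_left, specs)
      if (!is.null(res)) break
    }
    if (is.null(res)) break
    rounds <- rounds + 1L
    res$round <- rounds
    matches <- dplyr::bind_rows(matches, res[, c("target_id", "control_id", "round", "tier")])
    pool_left <- pool_left[!pool_left$exam_id %in% res$control_id, ]
  }
  new_matched_cohort(matches, targets$exam_id, rounds, specs)
}

new_matched_cohort <- function(matches, target_ids, rounds, specs = NULL) {
  structure(
    list(
      matches = matches,
      target_ids = target_ids,
      rounds_completed = rounds,
      ratio = rounds,
      bin_specs = specs
    ),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "<matched_cohort> %d targets, %d controls (1:%d over %d rounds)\n",
    length(x$target_ids), nrow(x$matches), x$ratio, x$rounds_completed
  ))
  invisible(x)
}

#' Tidy a matched cohort into its pair assignments
#'
#' @param x A `matched_cohort`.
#' @param ... Unused.
#' @return Tibble `target_id`, `control_id`, `round`, `tier` — one row per
#'   matched control with full provenance.
#' @method tidy matched_cohort
#' @export
tidy.matched_cohort <- function(x, ...) {
  x$matches
}

#' One-row summary of a matched cohort
#'
#' @param x A `matched_cohort`.
#' @param ... Unused.
#' @return Tibble with `n_targets`, `n_controls`, `rounds_completed`,
#'   `ratio`, `n_wide_tier`.
#' @method glance matched_cohort
#' @export
glance.matched_cohort <- function(x, ...) {
  tibble::tibble(
    n_targets = length(x$target_ids),
    n_controls = nrow(x$matches),
    rounds_completed = x$rounds_completed,
    ratio = x$ratio,
    n_wide_tier = sum(x$matches$tier == "wide")
  )
}

#' Control ids of a matched cohort
#' @param x A `matched_cohort`.
#' @return Character vector of matched control exam ids (no duplicates).
#' @export
control_ids <- function(x) {
  stopifnot(inherits(x, "matched_cohort"))
  x$matches$control_id
}

#' Match controls to every artifact-severity target group
#'
#' Target groups are the radiologist-graded mild, moderate and severe
#' examinations; the control pool is every optimal examination (radiologist
#' or model graded). Matching runs independently per category on a fresh
#' copy of the pool, so one control can serve several severity groups (but
#' never twice within one).
#'
#' @param exams Examination tibble with `exam_iq` and `iq_source` assigned.
#' @param seed Integer seed.
#' @param ... Passed on to [repeated_matching()] (`max_rounds`, ...).
#' @return Named list (`mild`, `moderate`, `severe`) of `matched_cohort`
#'   objects.
#' @export
match_all_categories <- function(exams, seed = 1, ...) {
  exams <- tibble::as_tibble(exams)
  if (!all(c("exam_iq", "iq_source") %in% names(exams)) ||
      anyNA(exams$exam_iq)) {
    rlang::abort("exam_iq/iq_source must be assigned for all exams (run grade_exams())",
                 class = "mricdr_precondition_error")
  }
  pool <- dplyr::filter(exams, .data$exam_iq == "optimal")
  out <- list()
  for (i in seq_along(c("mild", "moderate", "severe"))) {
    cat_i <- c("mild", "moderate", "severe")[i]
    targets <- dplyr::filter(
      exams, .data$exam_iq == cat_i, .data$iq_source == "radiologist"
    )
    if (nrow(targets) == 0) {
      rlang::warn(sprintf("no radiologist-graded %s examinations; empty matched cohort", cat_i))
      out[[cat_i]] <- new_matched_cohort(
        tibble::tibble(target_id = character(), control_id = character(),
                       round = integer(), tier = character()),
        character(), 0L
      )
    } else {
      out[[cat_i]] <- repeated_matching(
        targets, pool, seed = (seed * 131 + i) %% 2147483647, ...
      )
    }
  }
  out
}
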
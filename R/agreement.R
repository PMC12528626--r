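#' Landis-Koch verbal label for a kappa value
#'
#' Bands (after rounding half-up to 2 decimals): below 0.00 poor, 0.00-0.20
#' slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' 0.81-1.00 almost perfect.
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return Character label.
#' @export
#' @examples
#' label_kappa(c(0.64, 0.53, -0.1))
label_kappa <- function(kappa) {
  if (any(!is.na(kappa) & (kappa < -1 - 1e-9 | kappa > 1 + 1e-9))) {
    rlang::abort("kappa must lie in [-1, 1]", class = "mricdr_precondition_error")
  }
  k2 <- round_half_up(kappa, 2)
  dplyr::case_when(
    is.na(k2) ~ NA_character_,
    k2 < 0 ~ "poor",
    k2 <= 0.20 ~ "slight",
    k2 <= 0.40 ~ "fair",
    k2 <= 0.60 ~ "moderate",
    k2 <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

new_agreement_result <- function(kappa, kind, n_items, n_raters = NA_integer_,
                                 n_dropped = 0L, confusion = NULL) {
  structure(
    list(
      kappa = kappa,
      kind = kind,
      label = if (is.na(kappa)) NA_character_ else label_kappa(kappa),
      n_items = n_items,
      n_raters = n_raters,
      n_dropped = n_dropped,
      confusion = confusion
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s kappa = %s (%s), n = %d\n",
              x$kind,
              if (is.na(x$kappa)) "undefined" else sprintf("%.3f", x$kappa),
              x$label, x$n_items))
  invisible(x)
}

#' Tidy an agreement result
#' @param x An `agreement_result`.
#' @param ... Unused.
#' @return One-row tibble: `kappa`, `kind`, `label`, `n_items`, `n_raters`.
#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, kind = x$kind, label = x$label,
    n_items = x$n_items, n_raters = x$n_raters
  )
}

ratings_to_matrix <- function(ratings) {
  if (is.data.frame(ratings)) {
    need <- c("item", "rater", "category")
    if (!all(need %in% names(ratings))) {
      rlang::abort("long ratings need columns item, rater, category",
                   class = "mricdr_schema_error")
    }
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(ratings)[need],
      names_from = "rater", values_from = "category"
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$item
    m
  } else {
    as.matrix(ratings)
  }
}

#' Multi-rater generalized (Fleiss) kappa
#'
#' Chance-corrected agreement of m raters assigning n items to categories:
#' observed mean pairwise agreement against chance agreement from the
#' pooled category marginals. Items with any missing rating are dropped and
#' counted in `n_dropped`.
#'
#' @param ratings Items-by-raters matrix of categories, or a long tibble
#'   with columns `item`, `rater`, `category` (as written by
#'   [generate_ratings()]).
#' @param categories Category set; defaults to `iq_levels()` when all
#'   values are on the IQ scale, else the sorted observed values.
#' @return An `agreement_result` with `kind = "generalized_multirater"`.
#'   When a single category fills every cell, chance agreement is 1 and the
#'   kappa is flagged absent (`NA`).
#' @export
generalized_kappa <- function(ratings, categories = NULL) {
  m <- ratings_to_matrix(ratings)
  keep <- rowSums(is.na(m)) == 0
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("need >= 2 items and >= 2 raters with complete ratings",
                 class = "mricdr_precondition_error")
  }
  vals <- as.character(m)
  if (is.null(categories)) {
    categories <- if (all(vals %in% iq_levels())) iq_levels() else sort(unique(vals))
  }
  if (!all(vals %in% categories)) {
    rlang::abort("ratings outside the declared category set",
                 class = "mricdr_validation_error")
  }
  n <- nrow(m)
  r <- ncol(m)
  counts <- t(apply(m, 1, function(row) {
    as.integer(table(factor(row, levels = categories)))
  }))
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * r)
  p_e <- sum(p_j^2)
  kappa <- if (abs(1 - p_e) < 1e-12) {
    rlang::warn("single category used by all raters; kappa undefined")
    NA_real_
  } else {
    (p_bar - p_e) / (1 - p_e)
  }
  new_agreement_result(kappa, "generalized_multirater", n, r, n_dropped)
}

#' Weighted kappa from a confusion matrix
#'
#' `1 - sum(w * O) / sum(w * E)` with disagreement weights `w`, observed
#' cell proportions `O` and chance expectation `E` from the row/column
#' marginals. Quadratic weights `w_ij = (i - j)^2 / (k - 1)^2` (default)
#' penalise by squared ordinal distance; identity (0/1) weights recover
#' Cohen's unweighted kappa.
#'
#' @param confusion Square non-negative count matrix (rows = first source,
#'   columns = second source) with positive total.
#' @param weights `"quadratic"`, `"linear"` or `"identity"`.
#' @return An `agreement_result` with `kind = "weighted_quadratic"` (or the
#'   chosen weighting).
#' @export
weighted_kappa <- function(confusion, weights = c("quadratic", "linear", "identity")) {
  weights <- match.arg(weights)
  o <- as.matrix(confusion)
  if (nrow(o) != ncol(o) || any(o < 0)) {
    rlang::abort("confusion must be a square non-negative matrix",
                 class = "mricdr_precondition_error")
  }
  total <- sum(o)
  if (total == 0) {
    rlang::abort("confusion matrix has zero total", class = "mricdr_precondition_error")
  }
  k <- nrow(o)
  o <- o / total
  e <- outer(rowSums(o), colSums(o))
  idx <- seq_len(k)
  w <- switch(
    weights,
    quadratic = outer(idx, idx, function(i, j) (i - j)^2) / (k - 1)^2,
    linear = abs(outer(idx, idx, "-")) / (k - 1),
    identity = (outer(idx, idx, "-") != 0) * 1
  )
  denom <- sum(w * e)
  kappa <- if (denom < 1e-12) {
    rlang::warn("no chance disagreement; kappa undefined")
    NA_real_
  } else {
    1 - sum(w * o) / denom
  }
  new_agreement_result(
    kappa, paste0("weighted_", weights), n_items = total,
    confusion = confusion
  )
}

#' Confusion matrix of model predictions against radiologist assessments
#'
#' Rows are the reference (radiologist) category, columns the model
#' prediction; `col_props` holds per-cell proportions over the model's
#' prediction column.
#'
#' @param pred Predicted categories.
#' @param truth Reference categories (same length).
#' @param categories Category set; defaults as in [generalized_kappa()].
#' @return List with `counts` (k x k matrix), `col_props`, `n`.
#' @export
confusion_matrix <- function(pred, truth, categories = NULL) {
  if (length(pred) != length(truth)) {
    rlang::abort("pred and truth must have equal length",
                 class = "mricdr_precondition_error")
  }
  vals <- c(as.character(pred), as.character(truth))
  if (is.null(categories)) {
    categories <- if (all(vals %in% iq_levels())) iq_levels() else sort(unique(vals))
  }
  counts <- table(
    truth = factor(as.character(truth), levels = categories),
    pred = factor(as.character(pred), levels = categories)
  )
  counts <- unclass(counts)
  col_tot <- colSums(counts)
  col_props <- sweep(counts, 2, ifelse(col_tot == 0, 1, col_tot), "/")
  list(counts = counts, col_props = col_props, n = length(pred))
}
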
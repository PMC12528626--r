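#' Grade artifact severity from the obscured-prostate proportion
#'
#' The proportion of the gland obscured by gas-induced susceptibility
#' artifact is scored in 10% increments and converted to the four-point
#' scale: 0% -> optimal, 10% -> mild, 20% -> moderate, >= 30% -> severe.
#'
#' @param obscured_pct Numeric vector of percentages in `{0, 10, ..., 100}`.
#' @return Ordered IQ factor of the same length; `NA` in gives `NA` out.
#' @export
#' @examples
#' grade_from_proportion(c(0, 10, 20, 30, 100))
grade_from_proportion <- function(obscured_pct) {
  bad <- !is.na(obscured_pct) &
    (obscured_pct %% 10 != 0 | obscured_pct < 0 | obscured_pct > 100)
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "obscured_pct must be a multiple of 10 in [0, 100]; offending values: %s",
        paste(unique(obscured_pct[bad]), collapse = ", ")
      ),
      class = "mricdr_validation_error"
    )
  }
  code <- dplyr::case_when(
    is.na(obscured_pct) ~ NA_integer_,
    obscured_pct == 0 ~ 0L,
    obscured_pct == 10 ~ 1L,
    obscured_pct == 20 ~ 2L,
    TRUE ~ 3L
  )
  as_iq(code)
}

#' Median consensus of multiple ordinal ratings
#'
#' The consensus category is the median on the ordinal scale. With an even
#' number of raters the median can fall between two categories; the item is
#' then flagged for adjudication and resolved by `adjudication`: `"worse"`
#' (default; the more severe of the two middle ratings), `"better"`, or
#' `"error"` to refuse automatic resolution.
#'
#' @param ratings Vector of IQ categories (character, factor or 0-3 codes).
#' @param adjudication Off-scale median policy.
#' @return One-row tibble: `category` (ordered factor), `adjudication_needed`
#'   (logical), `n_raters`.
#' @export
#' @examples
#' consensus_rating(c("optimal", "mild", "mild"))
#' consensus_rating(c("optimal", "mild"))   # flagged, resolved to mild
consensus_rating <- function(ratings, adjudication = c("worse", "better", "error")) {
  adjudication <- match.arg(adjudication)
  codes <- iq_code(ratings)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    rlang::abort("consensus_rating() needs at least one rating",
                 class = "mricdr_precondition_error")
  }
  codes <- sort(codes)
  n <- length(codes)
  if (n %% 2 == 1) {
    mid <- codes[(n + 1) / 2]
    flagged <- FALSE
  } else {
    lo <- codes[n / 2]
    hi <- codes[n / 2 + 1]
    flagged <- lo != hi
    if (flagged && adjudication == "error") {
      rlang::abort(
        "median falls between two categories and adjudication = \"error\"",
        class = "mricdr_adjudication_error"
      )
    }
    mid <- if (adjudication == "better") lo else hi
    if (!flagged) mid <- lo
  }
  tibble::tibble(
    category = as_iq(mid),
    adjudication_needed = flagged,
    n_raters = n
  )
}

#' Examination-level IQ from series-level categories
#'
#' When an examination has several DWI series, the best (least severe)
#' series-level IQ defines the examination-level IQ.
#'
#' @param series_categories Vector of IQ categories, one per series.
#' @return Single ordered IQ factor: the minimum on the ordinal scale.
#' @export
exam_level_iq <- function(series_categories) {
  codes <- iq_code(series_categories)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    rlang::abort("exam_level_iq() needs at least one category",
                 class = "mricdr_precondition_error")
  }
  as_iq(min(codes))
}

#' Binarize IQ into poor vs acceptable
#'
#' Severe and moderate collapse to `poor`; mild and optimal to `acceptable`.
#'
#' @param category IQ categories.
#' @return Factor with levels `acceptable`, `poor`.
#' @export
binarize_iq <- function(category) {
  code <- iq_code(category)
  factor(
    ifelse(is.na(code), NA_character_,
           ifelse(code >= 2, "poor", "acceptable")),
    levels = c("acceptable", "poor")
  )
}

#' Reconcile radiologist and model categories per series
#'
#' For every series the radiologist assessment (the obscured-proportion
#' score if present, else the consensus of the `rater_*` columns) overrides
#' the model prediction; the model category is used only when no radiologist
#' assessment exists. Radiologist review is the ground truth the matching
#' targets are built from.
#'
#' @param series Series-level tibble (see [cohort()]).
#' @param adjudication Passed to [consensus_rating()] for even rater panels.
#' @return Tibble `exam_id`, `series_id`, `category` (ordered factor),
#'   `source` (`"radiologist"` or `"model"`), `adjudication_needed`.
#' @export
reconcile_categories <- function(series, adjudication = "worse") {
  series <- tibble::as_tibble(series)
  rater_cols <- grep("^rater_", names(series), value = TRUE)
  if (!"obscured_pct" %in% names(series)) series$obscured_pct <- NA_real_
  if (!"model_category" %in% names(series)) series$model_category <- NA_character_

  prop_cat <- grade_from_proportion(series$obscured_pct)

  cons_cat <- rep(NA_integer_, nrow(series))
  cons_flag <- rep(FALSE, nrow(series))
  if (length(rater_cols) > 0) {
    rater_mat <- as.matrix(series[rater_cols])
    need <- is.na(prop_cat) & rowSums(!is.na(rater_mat)) > 0
    for (i in which(need)) {
      cons <- consensus_rating(rater_mat[i, ], adjudication = adjudication)
      cons_cat[i] <- iq_code(cons$category)
      cons_flag[i] <- cons$adjudication_needed
    }
  }

  rad_code <- dplyr::coalesce(iq_code(prop_cat), cons_cat)
  model_code <- iq_code(as_iq(series$model_category))
  code <- dplyr::coalesce(rad_code, model_code)
  if (any(is.na(code))) {
    rlang::abort(
      sprintf("series without any IQ source at row(s) %s",
              paste(utils::head(which(is.na(code)), 10), collapse = ", ")),
      class = "mricdr_validation_error"
    )
  }
  tibble::tibble(
    exam_id = series$exam_id,
    series_id = series$series_id,
    category = as_iq(code),
    source = ifelse(!is.na(rad_code), "radiologist", "model"),
    adjudication_needed = cons_flag
  )
}

#' Assign examination-level IQ and its source
#'
#' Reconciles every series with [reconcile_categories()], then takes the
#' best (least severe) series category per examination; its source tags the
#' examination (`radiologist` preferred on ties). Stored `exam_iq` values
#' are kept unless `overwrite = TRUE`.
#'
#' @param x A [cohort()] with a series table.
#' @param adjudication Policy for even rater panels, see [consensus_rating()].
#' @param overwrite Recompute `exam_iq` even where already present.
#' @return The cohort with `exam_iq` and `iq_source` filled in `x$exams`.
#' @export
grade_exams <- function(x, adjudication = "worse", overwrite = FALSE) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(x$series)) {
    rlang::abort("cohort has no series table to grade from",
                 class = "mricdr_precondition_error")
  }
  rec <- reconcile_categories(x$series, adjudication = adjudication)
  best <- rec |>
    dplyr::mutate(
      code = iq_code(.data$category),
      rad = .data$source == "radiologist"
    ) |>
    dplyr::group_by(.data$exam_id) |>
    dplyr::summarise(
      new_iq = iq_levels()[min(.data$code) + 1L],
      new_source = if (any(.data$rad & .data$code == min(.data$code))) {
        "radiologist"
      } else {
        "model"
      },
      .groups = "drop"
    )
  exams <- x$exams
  if (!"exam_iq" %in% names(exams)) exams$exam_iq <- NA_character_
  if (!"iq_source" %in% names(exams)) exams$iq_source <- NA_character_
  exams <- exams |>
    dplyr::left_join(best, by = "exam_id") |>
    dplyr::mutate(
      use_new = overwrite | is.na(.data$exam_iq),
      exam_iq = ifelse(.data$use_new & !is.na(.data$new_iq),
                       .data$new_iq, .data$exam_iq),
      iq_source = ifelse(.data$use_new & !is.na(.data$new_iq),
                         .data$new_source, .data$iq_source)
    ) |>
    dplyr::select(-"new_iq", -"new_source", -"use_new")
  x$exams <- exams
  x
}
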
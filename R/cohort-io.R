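#' Cohort container: examination- and series-level tables
#'
#' A cohort bundles an examination-level tibble (one row per MRI examination:
#' demographics, PSA, facility, biopsy history, PI-RADS, pathology outcome)
#' with an optional series-level tibble (one row per DWI series: the
#' obscured-prostate proportion scored by radiologists, per-rater categories
#' in `rater_*` columns, and/or the model-predicted category).
#'
#' Examination columns: `exam_id`, `patient_id`, `age` (years), `psa`
#' (ng/mL, may be missing), `facility` (`I`/`II`/`III`), `biopsy_status`
#' (`naive`/`prev_benign`/`unknown`), `pirads` (1-5), `confirmed` (any
#' pathological diagnosis within the follow-up window), `cspca` (Grade
#' group >= 2 proven), `dominant_zone` (`PZ`/`TZ`/`none`), and optionally
#' `exam_iq` / `iq_source`.
#'
#' Series columns: `exam_id`, `series_id`, `obscured_pct` (multiples of 10
#' in 0..100, may be missing), `model_category`, plus any number of
#' `rater_<id>` columns holding IQ categories.
#'
#' @param exams Examination-level data frame.
#' @param series Optional series-level data frame.
#' @param provenance Free-text note on where the cohort came from.
#' @param validate Validate invariants (default `TRUE`).
#' @return An object of class `cohort`: a list with elements `exams`,
#'   `series` (possibly `NULL`) and `provenance`.
#' @export
cohort <- function(exams, series = NULL, provenance = "", validate = TRUE) {
  exams <- tibble::as_tibble(exams)
  if (!is.null(series)) series <- tibble::as_tibble(series)
  out <- structure(
    list(exams = exams, series = series, provenance = provenance),
    class = "cohort"
  )
  if (validate) validate_cohort(out)
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d examinations%s%s\n",
    nrow(x$exams),
    if (!is.null(x$series)) sprintf(", %d DWI series", nrow(x$series)) else "",
    if (nzchar(x$provenance)) paste0(" | ", x$provenance) else ""
  ))
  print(x$exams, n = 5)
  invisible(x)
}

exam_required_cols <- c(
  "exam_id", "patient_id", "age", "psa", "facility", "biopsy_status",
  "pirads", "confirmed", "cspca", "dominant_zone"
)
series_required_cols <- c("exam_id", "series_id", "obscured_pct", "model_category")

facility_levels <- c("I", "II", "III")
biopsy_levels <- c("naive", "prev_benign", "unknown")
zone_levels <- c("PZ", "TZ", "none")

#' Validate cohort invariants
#'
#' Checks every stated invariant and reports all offending rows at once with
#' row numbers; rows are never silently dropped.
#'
#' @param x A `cohort` object.
#' @return `x`, invisibly, if valid; otherwise aborts with a classed error
#'   (`mricdr_schema_error`, `mricdr_integrity_error` or
#'   `mricdr_validation_error`).
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  exams <- x$exams
  missing_cols <- setdiff(exam_required_cols, names(exams))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("exams table is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "mricdr_schema_error"
    )
  }
  dup <- exams$exam_id[duplicated(exams$exam_id)]
  if (length(dup) > 0) {
    rlang::abort(
      sprintf("duplicate exam_id: %s", paste(unique(dup), collapse = ", ")),
      class = "mricdr_integrity_error"
    )
  }

  problems <- character()
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf(
        "%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
        paste(utils::head(rows, 10), collapse = ", ")
      ))
    }
  }
  flag(is.na(exams$exam_id), "missing exam_id")
  flag(!is.na(exams$age) & exams$age <= 0, "age must be > 0")
  flag(is.na(exams$age), "missing age")
  flag(!is.na(exams$psa) & exams$psa < 0, "psa must be >= 0 when present")
  flag(!exams$facility %in% facility_levels, "facility must be one of I, II, III")
  flag(!exams$biopsy_status %in% biopsy_levels,
       "biopsy_status must be one of naive, prev_benign, unknown")
  flag(!is.na(exams$pirads) & !(exams$pirads %in% 1:5), "pirads must be 1..5")
  flag(!is.na(exams$cspca) & exams$cspca & !exams$confirmed,
       "cspca implies confirmed (proven cancer requires pathology)")
  flag(!exams$dominant_zone %in% zone_levels,
       "dominant_zone must be one of PZ, TZ, none")
  flag(exams$dominant_zone == "none" & exams$pirads >= 3,
       "dominant_zone 'none' allowed only when no lesion is reported (PI-RADS 1-2)")
  if ("exam_iq" %in% names(exams)) {
    flag(!is.na(exams$exam_iq) & !exams$exam_iq %in% iq_levels(),
         "exam_iq must be an IQ category")
  }

  series <- x$series
  if (!is.null(series)) {
    missing_cols <- setdiff(setdiff(series_required_cols, "obscured_pct"),
                            names(series))
    if (length(missing_cols) > 0) {
      rlang::abort(
        sprintf("series table is missing required column(s): %s",
                paste(missing_cols, collapse = ", ")),
        class = "mricdr_schema_error"
      )
    }
    if (!"obscured_pct" %in% names(series)) series$obscured_pct <- NA_real_
    sflag <- function(bad, msg) {
      if (any(bad, na.rm = TRUE)) {
        rows <- which(bad)
        problems <<- c(problems, sprintf(
          "series: %s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
          paste(utils::head(rows, 10), collapse = ", ")
        ))
      }
    }
    op <- series$obscured_pct
    sflag(!is.na(op) & (op %% 10 != 0 | op < 0 | op > 100),
          "obscured_pct must be a multiple of 10 in [0, 100]")
    sflag(!series$exam_id %in% exams$exam_id,
          "exam_id does not resolve to an examination")
    rater_cols <- grep("^rater_", names(series), value = TRUE)
    for (rc in rater_cols) {
      sflag(!is.na(series[[rc]]) & !series[[rc]] %in% iq_levels(),
            sprintf("%s holds a value outside the IQ scale", rc))
    }
    has_rating <- if (length(rater_cols) > 0) {
      rowSums(!is.na(series[rater_cols])) > 0
    } else {
      rep(FALSE, nrow(series))
    }
    sflag(is.na(op) & is.na(series$model_category) & !has_rating,
          "no IQ source present (need obscured_pct, rater category or model category)")
    if (!all(is.na(series$model_category))) {
      sflag(!is.na(series$model_category) &
              !series$model_category %in% iq_levels(),
            "model_category outside the IQ scale")
    }
  }

  if (length(problems) > 0) {
    rlang::abort(
      c("cohort validation failed:", stats::setNames(problems, rep("x", length(problems)))),
      class = "mricdr_validation_error"
    )
  }
  invisible(x)
}

exam_col_types <- function() {
  readr::cols(
    exam_id = readr::col_character(),
    patient_id = readr::col_character(),
    age = readr::col_double(),
    psa = readr::col_double(),
    facility = readr::col_character(),
    biopsy_status = readr::col_character(),
    pirads = readr::col_integer(),
    confirmed = readr::col_logical(),
    cspca = readr::col_logical(),
    dominant_zone = readr::col_character(),
    .default = readr::col_character()
  )
}

#' Read a cohort from delimited text
#'
#' Reads the examination table (and optionally the series table) from UTF-8
#' delimited text with a header row. Missing values are empty fields. A
#' stored `exam_iq` column is kept as-is; the loader never overwrites it
#' (re-grade explicitly with [grade_exams()] if wanted).
#'
#' @param exams_path Path to the examination-level file.
#' @param series_path Optional path to the series-level file.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(exams_path, series_path = NULL, delim = ",") {
  if (!file.exists(exams_path)) {
    rlang::abort(sprintf("file not found: %s", exams_path), class = "mricdr_io_error")
  }
  exams <- readr::read_delim(
    exams_path, delim = delim, col_types = exam_col_types(),
    na = "", show_col_types = FALSE, progress = FALSE
  )
  series <- NULL
  if (!is.null(series_path)) {
    if (!file.exists(series_path)) {
      rlang::abort(sprintf("file not found: %s", series_path), class = "mricdr_io_error")
    }
    series <- readr::read_delim(
      series_path, delim = delim,
      col_types = readr::cols(
        exam_id = readr::col_character(),
        series_id = readr::col_character(),
        obscured_pct = readr::col_double(),
        .default = readr::col_character()
      ),
      na = "", show_col_types = FALSE, progress = FALSE
    )
  }
  cohort(exams, series, provenance = sprintf("loaded from %s", exams_path))
}

#' Write a cohort to delimited text
#'
#' Writes files that [read_cohort()] accepts: stable column order, header
#' row, missing values (e.g. absent PSA) as empty fields, never a sentinel
#' number.
#'
#' @param x A `cohort`.
#' @param exams_path Output path for the examination table.
#' @param series_path Optional output path for the series table.
#' @param delim Field delimiter.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, exams_path, series_path = NULL, delim = ",") {
  stopifnot(inherits(x, "cohort"))
  lead <- intersect(c(exam_required_cols, "exam_iq", "iq_source"), names(x$exams))
  exams <- dplyr::select(x$exams, dplyr::all_of(lead), dplyr::everything())
  readr::write_delim(exams, exams_path, delim = delim, na = "")
  if (!is.null(series_path)) {
    if (is.null(x$series)) {
      rlang::abort("cohort has no series table to write", class = "mricdr_io_error")
    }
    lead <- intersect(series_required_cols, names(x$series))
    series <- dplyr::select(x$series, dplyr::all_of(lead), dplyr::everything())
    readr::write_delim(series, series_path, delim = delim, na = "")
  }
  invisible(x)
}
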
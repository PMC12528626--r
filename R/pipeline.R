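#' Configuration for an end-to-end pipeline run
#'
#' @param seed Global seed; per-stage sub-seeds are derived from it with a
#'   fixed splitting rule so each stage is individually reproducible.
#' @param sim A [sim_config()] used when no input cohort is given.
#' @param input A [cohort()] to analyse instead of simulating.
#' @param max_rounds Matching rounds cap per severity category.
#' @param zones Zone subgroups to analyse (subset of `c("PZ", "TZ")`, or
#'   `NULL` for none).
#' @param adjudication Policy for even rater panels, see
#'   [consensus_rating()].
#' @param out_dir Optional directory; when set, intermediate tables (CSV),
#'   the report and the manifest (JSON) are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, sim = sim_config(), input = NULL,
                       max_rounds = 20, zones = c("PZ", "TZ"),
                       adjudication = "worse", out_dir = NULL) {
  if (!is.null(zones)) stopifnot(all(zones %in% c("PZ", "TZ")))
  structure(
    list(seed = seed, sim = sim, input = input, max_rounds = max_rounds,
         zones = zones, adjudication = adjudication, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full matched-cohort CDR analysis
#'
#' Orchestrates: simulate (or take the supplied cohort) -> grade exam-level
#' IQ -> match optimal controls to each severity group -> balance
#' diagnostics -> diagnostic metrics, ratios and chi-squared per severity
#' (and per zone subgroup). Every stage is a pure function of its inputs
#' and the stage sub-seed, so a fixed configuration reproduces the bundle
#' exactly.
#'
#' @param config A [run_config()].
#' @return A `cdr_report` list: `cohort` (graded), `matched` (per
#'   severity), `balance` (per severity tibble), `metrics` (per severity:
#'   `target`, `control`, `ratios`), `zones` (per zone, same shape),
#'   `log` (stage-by-stage counts), `manifest` (resolved configuration and
#'   sub-seeds).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(
    simulate = stage_seed(config$seed, "simulate"),
    match = stage_seed(config$seed, "match")
  )
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, message = msg)
  }

  co <- if (is.null(config$input)) {
    out <- generate_cohort(config$sim, seed = seeds$simulate)
    note("simulate", sprintf("generated %d exams, %d series",
                             nrow(out$exams), nrow(out$series)))
    out
  } else {
    note("load", sprintf("using supplied cohort of %d exams", nrow(config$input$exams)))
    config$input
  }

  co <- grade_exams(co, adjudication = config$adjudication)
  note("grade", sprintf(
    "exam-level IQ: %s",
    paste(sprintf("%s %d", iq_levels(),
                  as.integer(table(factor(co$exams$exam_iq, iq_levels())))),
          collapse = ", ")
  ))

  matched <- withr::with_seed(
    seeds$match,
    suppressWarnings(match_all_categories(
      co$exams, seed = seeds$match, max_rounds = config$max_rounds
    ))
  )
  for (cat_i in names(matched)) {
    note("match", sprintf(
      "%s: %d targets, %d controls (1:%d)", cat_i,
      length(matched[[cat_i]]$target_ids), nrow(matched[[cat_i]]$matches),
      matched[[cat_i]]$ratio
    ))
  }

  analyse_sets <- function(exam_tbl) {
    res <- list()
    for (cat_i in names(matched)) {
      mc <- matched[[cat_i]]
      t_df <- exam_tbl[exam_tbl$exam_id %in% mc$target_ids, ]
      c_df <- exam_tbl[exam_tbl$exam_id %in% control_ids(mc), ]
      if (nrow(t_df) == 0 || nrow(c_df) == 0) {
        res[[cat_i]] <- NULL
        next
      }
      tm <- compute_metrics(t_df)
      cm <- compute_metrics(c_df)
      res[[cat_i]] <- list(target = tm, control = cm,
                           ratios = compare_groups(tm, cm))
    }
    res
  }

  balance <- list()
  for (cat_i in names(matched)) {
    mc <- matched[[cat_i]]
    balance[[cat_i]] <- if (length(mc$target_ids) > 0 && nrow(mc$matches) > 0) {
      balance_table(co$exams, mc)
    } else {
      NULL
    }
  }
  metrics <- analyse_sets(co$exams)
  zones <- list()
  for (z in config$zones %||% character()) {
    zones[[z]] <- analyse_sets(suppressWarnings(zone_subgroup(co$exams, z)))
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = seeds,
    sim = if (is.null(config$input)) unclass(config$sim) else NULL,
    max_rounds = config$max_rounds,
    zones = config$zones,
    adjudication = config$adjudication
  )
  report <- structure(
    list(cohort = co, matched = matched, balance = balance,
         metrics = metrics, zones = zones,
         log = dplyr::bind_rows(log), manifest = manifest),
    class = "cdr_report"
  )
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  report
}

#' @export
print.cdr_report <- function(x, ...) {
  cat("<cdr_report>\n")
  print(x$log, n = Inf)
  invisible(x)
}

#' Tidy a pipeline report into severity-level results
#'
#' @param x A `cdr_report`.
#' @param ... Unused.
#' @return Tibble with one row per severity group and metric ratio,
#'   including the chi-squared p-value for the CDR comparison.
#' @method tidy cdr_report
#' @export
tidy.cdr_report <- function(x, ...) {
  purrr::imap_dfr(x$metrics, function(m, nm) {
    generics::tidy(m$ratios) |>
      dplyr::mutate(
        severity = nm,
        chi2_p = m$ratios$chi2_p,
        n_targets = m$target$n_exams,
        n_controls = m$control$n_exams
      )
  }) |>
    dplyr::select("severity", dplyr::everything())
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort,
               file.path(out_dir, "exams_graded.csv"),
               file.path(out_dir, "series.csv"))
  for (cat_i in names(report$matched)) {
    readr::write_csv(generics::tidy(report$matched[[cat_i]]),
                     file.path(out_dir, sprintf("matched_%s.csv", cat_i)), na = "")
    if (!is.null(report$balance[[cat_i]])) {
      readr::write_csv(report$balance[[cat_i]],
                       file.path(out_dir, sprintf("balance_%s.csv", cat_i)), na = "")
    }
  }
  jsonlite::write_json(
    list(
      manifest = report$manifest,
      results = lapply(report$metrics, function(m) {
        list(target = generics::glance(m$target),
             control = generics::glance(m$control),
             ratios = generics::glance(m$ratios))
      }),
      zones = lapply(report$zones, function(zz) {
        lapply(zz, function(m) list(ratios = generics::glance(m$ratios)))
      }),
      log = report$log
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(report)
}
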
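# Fixture factories shared across tests; everything built in code.

make_exams <- function(n = 6, seed = NULL,
                       facility = NULL, biopsy = NULL,
                       age = NULL, psa = NULL, pirads = NULL,
                       confirmed = NULL, cspca = NULL, zone = NULL,
                       exam_iq = NULL, iq_source = NULL, prefix = "E") {
  if (!is.null(seed)) set.seed(seed)
  pirads <- pirads %||% rep(2L, n)
  cspca <- cspca %||% rep(FALSE, n)
  confirmed <- confirmed %||% cspca
  zone <- zone %||% ifelse(pirads >= 3, "PZ", "none")
  tibble::tibble(
    exam_id = sprintf("%s%04d", prefix, seq_len(n)),
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age %||% round(runif(n, 50, 80), 1),
    psa = psa %||% round(exp(rnorm(n, log(6), 0.5)), 1),
    facility = facility %||% sample(c("I", "II", "III"), n, replace = TRUE),
    biopsy_status = biopsy %||% sample(c("naive", "prev_benign", "unknown"), n,
                                       replace = TRUE),
    pirads = as.integer(pirads),
    confirmed = confirmed,
    cspca = cspca,
    dominant_zone = zone,
    exam_iq = exam_iq %||% rep(NA_character_, n),
    iq_source = iq_source %||% rep(NA_character_, n)
  )
}

make_series <- function(exam_ids, obscured_pct = NA_real_,
                        model_category = "optimal") {
  n <- length(exam_ids)
  tibble::tibble(
    exam_id = exam_ids,
    series_id = paste0(exam_ids, "_S1"),
    obscured_pct = rep_len(obscured_pct, n),
    model_category = rep_len(model_category, n)
  )
}

# random valid cohort for round-trip property tests
random_cohort <- function(n = 20, seed = 1) {
  set.seed(seed)
  cspca <- runif(n) < 0.3
  pirads <- ifelse(cspca, sample(3:5, n, replace = TRUE),
                   sample(1:5, n, replace = TRUE))
  confirmed <- cspca | (runif(n) < 0.4)
  zone <- ifelse(pirads >= 3, sample(c("PZ", "TZ"), n, replace = TRUE), "none")
  exams <- make_exams(
    n, facility = sample(c("I", "II", "III"), n, TRUE),
    psa = ifelse(runif(n) < 0.2, NA_real_, round(runif(n, 1, 30), 1)),
    pirads = pirads, confirmed = confirmed, cspca = cspca, zone = zone,
    exam_iq = sample(iq_levels(), n, TRUE),
    iq_source = sample(c("radiologist", "model"), n, TRUE)
  )
  series <- tibble::tibble(
    exam_id = exams$exam_id,
    series_id = paste0(exams$exam_id, "_S1"),
    obscured_pct = sample(c(NA, seq(0, 100, 10)), n, replace = TRUE),
    model_category = sample(iq_levels(), n, replace = TRUE)
  )
  cohort(exams, series, provenance = "fixture")
}

# targets plus `copies` exact clones of each as the control pool
cloned_pool <- function(targets, copies) {
  purrr::map_dfr(seq_len(copies), function(k) {
    dplyr::mutate(
      targets,
      exam_id = sprintf("C%02d_%s", k, .data$exam_id),
      patient_id = sprintf("CP%02d_%s", k, .data$patient_id)
    )
  })
}
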
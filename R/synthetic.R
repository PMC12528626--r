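#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of a large multi-center prostate
#' MRI population: three facilities, log-normal PSA with ~18% missingness,
#' ~25% proven csPCa prevalence, a heavily optimal-skewed artifact severity
#' distribution, and PI-RADS assignment whose sensitivity to csPCa may
#' depend on examination-level IQ. See the methods vignette for the
#' provenance of each default.
#'
#' @param n_exams Number of examinations.
#' @param facility_probs Probabilities for facilities I, II, III.
#' @param age_mean,age_sd Age distribution (years); draws truncated to
#'   `[30, 95]`.
#' @param psa_log_mean,psa_log_sd Natural-log-scale PSA parameters (ng/mL).
#' @param psa_missing_frac Fraction of examinations with missing PSA.
#' @param iq_probs Probabilities of the planted examination-level IQ,
#'   in `iq_levels()` order.
#' @param series_per_exam_probs Distribution of the DWI series count over
#'   `{1, 2, 3}`.
#' @param biopsy_status_probs Probabilities for naive / prev_benign / unknown.
#' @param cspca_base_prev Baseline proven-csPCa prevalence (logistic
#'   intercept is its logit).
#' @param confounder_strengths Named numeric: `age` (log-odds per SD of
#'   age), `log_psa` (log-odds per SD of log PSA), `facility_II`,
#'   `facility_III` (offsets vs facility I). All zero gives marginal
#'   prevalence exactly `cspca_base_prev`.
#' @param detection_sensitivity_by_iq Probability a csPCa examination is
#'   assigned PI-RADS >= 3, per IQ category (length 4).
#' @param false_positive_rate_by_iq Probability a non-csPCa examination is
#'   assigned PI-RADS >= 3, per IQ category.
#' @param confirmation_prob_given_pirads3plus Probability a non-csPCa
#'   PI-RADS >= 3 examination gets pathological work-up.
#' @param systematic_biopsy_prob_given_pirads12 Probability a non-csPCa
#'   PI-RADS 1-2 examination gets a systematic biopsy.
#' @param zone_pz_frac Fraction of csPCa that is peripheral-zone dominant.
#' @param radiologist_review_frac Fraction of series reviewed by
#'   radiologists irrespective of predicted category (emulating a random
#'   reader-study sample).
#' @param moderate_review_frac Fraction of model-predicted moderate series
#'   additionally reviewed by radiologists; severe predictions are always
#'   reviewed. Mirrors a targeted review of the worst-quality predictions,
#'   which keeps poor-quality target groups small relative to the optimal
#'   control pool.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_exams = 2000,
                       facility_probs = c(0.531, 0.215, 0.254),
                       age_mean = 65.5, age_sd = 8.4,
                       psa_log_mean = log(6.3), psa_log_sd = 0.5,
                       psa_missing_frac = 0.177,
                       iq_probs = c(0.528, 0.366, 0.098, 0.008),
                       series_per_exam_probs = c(0.95, 0.04, 0.01),
                       biopsy_status_probs = c(0.308, 0.302, 0.390),
                       cspca_base_prev = 0.25,
                       confounder_strengths = c(age = 0.35, log_psa = 0.6,
                                                facility_II = 0.1,
                                                facility_III = -0.1),
                       detection_sensitivity_by_iq = c(0.95, 0.95, 0.93, 0.87),
                       false_positive_rate_by_iq = c(0.28, 0.28, 0.28, 0.28),
                       confirmation_prob_given_pirads3plus = 0.6,
                       systematic_biopsy_prob_given_pirads12 = 0.1,
                       zone_pz_frac = 0.8,
                       radiologist_review_frac = 0.05,
                       moderate_review_frac = 0.16) {
  cfg <- list(
    n_exams = n_exams,
    facility_probs = facility_probs,
    age_mean = age_mean, age_sd = age_sd,
    psa_log_mean = psa_log_mean, psa_log_sd = psa_log_sd,
    psa_missing_frac = psa_missing_frac,
    iq_probs = iq_probs,
    series_per_exam_probs = series_per_exam_probs,
    biopsy_status_probs = biopsy_status_probs,
    cspca_base_prev = cspca_base_prev,
    confounder_strengths = confounder_strengths,
    detection_sensitivity_by_iq = detection_sensitivity_by_iq,
    false_positive_rate_by_iq = false_positive_rate_by_iq,
    confirmation_prob_given_pirads3plus = confirmation_prob_given_pirads3plus,
    systematic_biopsy_prob_given_pirads12 = systematic_biopsy_prob_given_pirads12,
    zone_pz_frac = zone_pz_frac,
    radiologist_review_frac = radiologist_review_frac,
    moderate_review_frac = moderate_review_frac
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(p, what, len = NULL) {
    if (!is.null(len) && length(p) != len) {
      rlang::abort(sprintf("%s must have length %d", what, len),
                   class = "mricdr_config_error")
    }
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      rlang::abort(sprintf("%s must be probabilities in [0, 1]", what),
                   class = "mricdr_config_error")
    }
  }
  chk_simplex <- function(p, what, len) {
    chk_prob(p, what, len)
    if (abs(sum(p) - 1) > 1e-6) {
      rlang::abort(sprintf("%s must sum to 1", what),
                   class = "mricdr_config_error")
    }
  }
  if (cfg$n_exams < 0) {
    rlang::abort("n_exams must be >= 0", class = "mricdr_config_error")
  }
  chk_simplex(cfg$facility_probs, "facility_probs", 3)
  chk_simplex(cfg$iq_probs, "iq_probs", 4)
  chk_simplex(cfg$series_per_exam_probs, "series_per_exam_probs", 3)
  chk_simplex(cfg$biopsy_status_probs, "biopsy_status_probs", 3)
  chk_prob(cfg$psa_missing_frac, "psa_missing_frac", 1)
  chk_prob(cfg$cspca_base_prev, "cspca_base_prev", 1)
  chk_prob(cfg$detection_sensitivity_by_iq, "detection_sensitivity_by_iq", 4)
  chk_prob(cfg$false_positive_rate_by_iq, "false_positive_rate_by_iq", 4)
  chk_prob(cfg$confirmation_prob_given_pirads3plus,
           "confirmation_prob_given_pirads3plus", 1)
  chk_prob(cfg$systematic_biopsy_prob_given_pirads12,
           "systematic_biopsy_prob_given_pirads12", 1)
  chk_prob(cfg$zone_pz_frac, "zone_pz_frac", 1)
  chk_prob(cfg$radiologist_review_frac, "radiologist_review_frac", 1)
  chk_prob(cfg$moderate_review_frac, "moderate_review_frac", 1)
  if (cfg$age_sd <= 0 || cfg$psa_log_sd <= 0) {
    rlang::abort("scale parameters must be positive", class = "mricdr_config_error")
  }
  invisible(cfg)
}

# severe series get an obscured proportion >= 30, concentrated in 30-40
# (roughly four fifths of severe gland obscuration falls there).
severe_pct_probs <- c(0.45, 0.33, 0.10, 0.05, 0.04, 0.02, 0.006, 0.004)

#' Generate a synthetic cohort
#'
#' Draws examinations (confounders, latent disease, PI-RADS, pathology) and
#' their DWI series (planted IQ categories, obscured proportions, model
#' predictions) under the generative model described in the methods
#' vignette. The examination-level IQ equals the best (minimum) series
#' category by construction; detection of csPCa depends on it only through
#' `detection_sensitivity_by_iq`. Proven csPCa is the disease draw itself
#' and is always pathologically confirmed; non-csPCa examinations are
#' confirmed with the PI-RADS-dependent probabilities.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; fixed seed gives an identical cohort.
#' @return A [cohort()] with exams (including planted `exam_iq`,
#'   `iq_source`) and series tables.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  n <- config$n_exams
  if (n == 0) {
    exams <- tibble::tibble(
      exam_id = character(), patient_id = character(), age = numeric(),
      psa = numeric(), facility = character(), biopsy_status = character(),
      pirads = integer(), confirmed = logical(), cspca = logical(),
      dominant_zone = character(), exam_iq = character(),
      iq_source = character()
    )
    series <- tibble::tibble(
      exam_id = character(), series_id = character(),
      obscured_pct = numeric(), model_category = character()
    )
    return(cohort(exams, series, provenance = "synthetic (empty)"))
  }
  withr::local_seed(seed)
  lv <- iq_levels()

  facility <- sample(facility_levels, n, replace = TRUE, prob = config$facility_probs)
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 30), 95)
  log_psa <- stats::rnorm(n, config$psa_log_mean, config$psa_log_sd)
  psa <- round(exp(log_psa), 1)
  psa_missing <- stats::runif(n) < config$psa_missing_frac
  biopsy_status <- sample(biopsy_levels, n, replace = TRUE,
                          prob = config$biopsy_status_probs)

  exam_code <- sample(0:3, n, replace = TRUE, prob = config$iq_probs)

  cs <- config$confounder_strengths
  get0n <- function(nm) if (!is.null(cs[nm]) && !is.na(cs[nm])) cs[[nm]] else 0
  eta <- stats::qlogis(config$cspca_base_prev) +
    get0n("age") * (age - config$age_mean) / config$age_sd +
    get0n("log_psa") * (log_psa - config$psa_log_mean) / config$psa_log_sd +
    get0n("facility_II") * (facility == "II") +
    get0n("facility_III") * (facility == "III")
  cspca <- stats::runif(n) < stats::plogis(eta)

  sens <- config$detection_sensitivity_by_iq[exam_code + 1L]
  fpr <- config$false_positive_rate_by_iq[exam_code + 1L]
  detected <- ifelse(cspca, stats::runif(n) < sens, stats::runif(n) < fpr)

  pirads <- integer(n)
  pirads[detected & cspca] <- sample(3:5, sum(detected & cspca), replace = TRUE,
                                     prob = c(0.2, 0.45, 0.35))
  pirads[detected & !cspca] <- sample(3:4, sum(detected & !cspca), replace = TRUE,
                                      prob = c(0.7, 0.3))
  pirads[!detected] <- sample(1:2, sum(!detected), replace = TRUE,
                              prob = c(0.6, 0.4))

  # csPCa is proven within the pathology window by definition of the
  # indicator; work-up of the rest depends on PI-RADS.
  confirmed <- cspca |
    (pirads >= 3 & stats::runif(n) < config$confirmation_prob_given_pirads3plus) |
    (pirads < 3 & stats::runif(n) < config$systematic_biopsy_prob_given_pirads12)

  dominant_zone <- dplyr::case_when(
    cspca ~ ifelse(stats::runif(n) < config$zone_pz_frac, "PZ", "TZ"),
    pirads >= 3 ~ ifelse(stats::runif(n) < 0.7, "PZ", "TZ"),
    TRUE ~ "none"
  )

  exams <- tibble::tibble(
    exam_id = sprintf("E%05d", seq_len(n)),
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    psa = ifelse(psa_missing, NA_real_, psa),
    facility = facility,
    biopsy_status = biopsy_status,
    pirads = pirads,
    confirmed = confirmed,
    cspca = cspca,
    dominant_zone = dominant_zone
  )

  n_series <- sample(1:3, n, replace = TRUE, prob = config$series_per_exam_probs)
  series <- tibble::tibble(
    exam_id = rep(exams$exam_id, n_series),
    idx = sequence(n_series),
    exam_code = rep(exam_code, n_series)
  )
  # first series carries the planted exam category; extra series are drawn
  # from the equal-or-worse categories so the best series defines the exam.
  extra <- series$idx > 1
  series$code <- series$exam_code
  if (any(extra)) {
    series$code[extra] <- vapply(series$exam_code[extra], function(c0) {
      cats <- c0:3
      p <- config$iq_probs[cats + 1L]
      cats[sample.int(length(cats), 1, prob = p)]
    }, integer(1))
  }
  u <- stats::runif(nrow(series))
  reviewed <- series$code == 3 |
    (series$code == 2 & u < config$moderate_review_frac) |
    u < config$radiologist_review_frac
  obscured <- rep(NA_real_, nrow(series))
  rv_sev <- which(reviewed & series$code == 3)
  rv_rest <- which(reviewed & series$code < 3)
  obscured[rv_rest] <- series$code[rv_rest] * 10
  obscured[rv_sev] <- sample(seq(30, 100, 10), length(rv_sev), replace = TRUE,
                             prob = severe_pct_probs)
  series_tbl <- tibble::tibble(
    exam_id = series$exam_id,
    series_id = sprintf("%s_S%d", series$exam_id, series$idx),
    obscured_pct = obscured,
    model_category = lv[series$code + 1L]
  )

  exam_best <- series |>
    dplyr::mutate(rad = reviewed) |>
    dplyr::group_by(.data$exam_id) |>
    dplyr::summarise(
      best = min(.data$code),
      rad_best = any(.data$rad & .data$code == min(.data$code)),
      .groups = "drop"
    )
  exams <- exams |>
    dplyr::left_join(exam_best, by = "exam_id") |>
    dplyr::mutate(
      exam_iq = lv[.data$best + 1L],
      iq_source = ifelse(.data$rad_best, "radiologist", "model")
    ) |>
    dplyr::select(-"best", -"rad_best")

  cohort(exams, series_tbl,
         provenance = sprintf("synthetic cohort (n = %d, seed = %d)", n, seed))
}

#' Generate multi-rater ordinal ratings from a confusion model
#'
#' Each rater independently draws a category conditional on the item's true
#' category through a 4x4 row-stochastic confusion matrix (rows = truth,
#' columns = assigned category, in `iq_levels()` order).
#'
#' @param true_categories Vector of true IQ categories (length = items).
#' @param n_raters Number of raters.
#' @param confusion 4x4 row-stochastic matrix; the identity reproduces the
#'   truth exactly.
#' @param seed Integer seed.
#' @return Long tibble `item`, `rater`, `category` suitable for
#'   [generalized_kappa()].
#' @export
generate_ratings <- function(true_categories, n_raters, confusion, seed = 1) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4, 4)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8)) {
    rlang::abort("confusion must be a 4x4 row-stochastic matrix",
                 class = "mricdr_config_error")
  }
  withr::local_seed(seed)
  truth <- iq_code(true_categories)
  n_items <- length(truth)
  lv <- iq_levels()
  out <- tidyr::expand_grid(item = seq_len(n_items), rater = seq_len(n_raters))
  out$category <- vapply(out$item, function(i) {
    sample(lv, 1, prob = confusion[truth[i] + 1L, ])
  }, character(1))
  out |>
    dplyr::mutate(
      item = sprintf("I%04d", .data$item),
      rater = sprintf("R%02d", .data$rater)
    )
}
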
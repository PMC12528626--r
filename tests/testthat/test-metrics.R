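test_that("metrics from the large-cohort counts reproduce the printed rates", {
  m <- diag_metrics(12947, 5790, NA, 3065)
  expect_equal(round(m$cdr$estimate, 2), 0.24)
  expect_equal(round(m$air$estimate, 2), 0.45)
  expect_true(is.na(m$ppv$estimate))
  expect_true(is.na(m$confirmation_rate$estimate))
})

test_that("zero denominators yield absent metrics, never zero-divisions", {
  ex <- make_exams(10, seed = 1, pirads = rep(1:2, 5))
  m <- compute_metrics(ex)
  expect_equal(m$air$estimate, 0)
  expect_equal(m$cdr$estimate, 0)
  expect_true(is.na(m$ppv$estimate))
  expect_true(is.na(m$confirmation_rate$estimate))
  expect_error(compute_metrics(ex[0, ]), class = "mricdr_precondition_error")
  expect_error(diag_metrics(10, 12, 5, 3), class = "mricdr_validation_error")
})

test_that("CDR factorizes exactly into AIR x PPV x confirmation rate on counts", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(50:5000, 1)
    abn <- sample(0:n, 1)
    conf <- if (abn > 0) sample(1:abn, 1) else 0
    det <- if (conf > 0) sample(0:conf, 1) else 0
    m <- diag_metrics(n, abn, conf, det)
    if (!is.na(m$ppv$estimate)) {
      expect_equal(
        m$cdr$estimate,
        m$air$estimate * m$ppv$estimate * m$confirmation_rate$estimate
      )
    }
  }
})

test_that("the factorization identity holds on synthetic cohorts, and CDR <= AIR", {
  for (seed in c(4, 5)) {
    ex <- generate_cohort(sim_config(n_exams = 4000), seed = seed)$exams
    m <- compute_metrics(ex)
    expect_equal(m$cdr$estimate,
                 m$air$estimate * m$ppv$estimate * m$confirmation_rate$estimate)
    expect_lte(m$cdr$estimate, m$air$estimate)
    expect_true(m$ppv$estimate >= 0 && m$ppv$estimate <= 1)
    expect_true(m$confirmation_rate$estimate >= 0 &&
                  m$confirmation_rate$estimate <= 1)
  }
})

test_that("identical groups give unit ratios and a null chi-squared", {
  m <- diag_metrics(400, 180, 120, 90)
  r <- compare_groups(m, m)
  td <- tidy(r)
  expect_equal(td$estimate, rep(1, 4))
  expect_equal(r$chi2_p, 1)
})

test_that("the chi-squared comparison matches the hand-computed Pearson statistic", {
  # 30 detected of 120 vs 45 of 130: X2 = n(ad-bc)^2 / (r1 r2 c1 c2)
  t_m <- diag_metrics(120, 60, 40, 30)
  c_m <- diag_metrics(130, 70, 55, 45)
  r <- compare_groups(t_m, c_m)
  expect_equal(r$chi2_statistic, 2.7472527472527473, tolerance = 1e-12)
  expect_equal(r$chi2_p, 0.09742168927634332, tolerance = 1e-10)
})

test_that("ratio factorization is exact and the Katz interval brackets the estimate", {
  set.seed(6)
  for (i in 1:15) {
    mk <- function() {
      n <- sample(100:2000, 1)
      abn <- sample(10:n, 1)
      conf <- sample(5:abn, 1)
      det <- sample(1:conf, 1)
      diag_metrics(n, abn, conf, det)
    }
    r <- compare_groups(mk(), mk())
    expect_equal(
      r$cdr_ratio$estimate,
      r$air_ratio$estimate * r$ppv_ratio$estimate * r$confirmation_ratio$estimate
    )
    expect_lte(r$cdr_ratio$conf_low, r$cdr_ratio$estimate)
    expect_gte(r$cdr_ratio$conf_high, r$cdr_ratio$estimate)
  }
})

test_that("a zero control component leaves the ratio absent with a warning", {
  t_m <- diag_metrics(100, 40, 30, 20)
  c_m <- diag_metrics(100, 40, 30, 0)
  ws <- testthat::capture_warnings(r <- compare_groups(t_m, c_m))
  expect_true(any(grepl("absent", ws)))
  expect_true(is.na(r$cdr_ratio$estimate))
  expect_false(is.na(r$air_ratio$estimate))
})

test_that("zone subgroups exclude only proven csPCa dominant in the other zone", {
  ex <- make_exams(
    4, seed = 7, pirads = c(4L, 4L, 4L, 2L),
    cspca = c(TRUE, TRUE, FALSE, FALSE),
    confirmed = c(TRUE, TRUE, TRUE, FALSE),
    zone = c("TZ", "PZ", "TZ", "none")
  )
  pz <- zone_subgroup(ex, "PZ")
  expect_setequal(pz$exam_id, c("E0002", "E0003", "E0004"))
  tz <- zone_subgroup(ex, "TZ")
  expect_setequal(tz$exam_id, c("E0001", "E0003", "E0004"))
  odd <- ex
  odd$pirads[1] <- 2L
  odd$dominant_zone[1] <- "none"
  expect_warning(keep <- zone_subgroup(odd, "PZ"), "without a dominant zone")
  expect_true("E0001" %in% keep$exam_id)
})

test_that("factor association cross-tabulates binarized IQ with the right tests", {
  ex <- make_exams(200, seed = 8,
                   exam_iq = rep(c("severe", "optimal"), each = 100))
  # identical facility distribution across strata -> p ~ 1
  ex$facility <- rep(rep(c("I", "II", "III", "I"), 25), 2)
  fa <- factor_association(ex, "facility")
  expect_gt(fa$p_value, 0.99)
  # 2x3 oracle: brute-force expected counts
  ex2 <- make_exams(120, seed = 9, exam_iq = rep(c("moderate", "mild"), 60))
  ex2$facility <- sample(c("I", "II", "III"), 120, TRUE)
  fa2 <- factor_association(ex2, "facility")
  tab <- table(binarize_iq(ex2$exam_iq), ex2$facility)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(fa2$statistic, sum((tab - expected)^2 / expected))
  # constant continuous factor -> undefined, flagged
  ex2$age <- 65
  fa3 <- factor_association(ex2, "age")
  expect_false(fa3$defined)
  expect_true(is.na(fa3$p_value))
  # wilcoxon route runs for skewed variables
  fa4 <- factor_association(ex2, "psa", test = "wilcox")
  expect_true(fa4$defined)
})
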
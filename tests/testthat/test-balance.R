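test_that("continuous SMD reproduces the published age imbalances", {
  expect_equal(round(smd_continuous(67.0, 10.1, 65.3, 8.2), 2), 0.18)
  expect_equal(round(smd_continuous(65.7, 10.3, 65.3, 8.2), 2), 0.04)
  expect_equal(smd_continuous(60, 5, 60, 5), 0)
  expect_equal(smd_continuous(60, 0, 60, 0), 0)
  expect_error(smd_continuous(61, 0, 60, 0), class = "mricdr_validation_error")
})

test_that("continuous SMD is sign-symmetric and affine-invariant", {
  set.seed(1)
  for (i in 1:10) {
    mt <- runif(1, 50, 80); st <- runif(1, 1, 15)
    mc <- runif(1, 50, 80); sc <- runif(1, 1, 15)
    s <- smd_continuous(mt, st, mc, sc)
    expect_equal(smd_continuous(mc, sc, mt, st), -s)
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    expect_equal(smd_continuous(a * mt + b, a * st, a * mc + b, a * sc), s)
  }
})

test_that("categorical SMD matches the binary closed form and a hand-computed case", {
  expect_equal(smd_categorical(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # two categories reduce to the standard binary-proportion SMD (magnitude)
  set.seed(2)
  for (i in 1:10) {
    p1 <- runif(1, 0.05, 0.95); p2 <- runif(1, 0.05, 0.95)
    binary <- abs(p1 - p2) / sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    expect_equal(smd_categorical(c(p1, 1 - p1), c(p2, 1 - p2)), binary)
  }
  # independent hand computation: (0.5,0.5) vs (0.9,0.1)
  expect_equal(smd_categorical(c(0.5, 0.5), c(0.9, 0.1)), 0.9701425, tolerance = 1e-6)
})

test_that("categorical SMD reproduces the published facility and biopsy imbalances", {
  expect_equal(round(smd_categorical(c(0.454, 0.504, 0.043),
                                     c(0.531, 0.215, 0.254)), 2), 0.80)
  expect_equal(round(smd_categorical(c(0.333, 0.213, 0.454),
                                     c(0.308, 0.302, 0.390)), 2), 0.21)
  expect_equal(round(smd_categorical(c(0.497, 0.354, 0.149),
                                     c(0.531, 0.215, 0.254)), 2), 0.36)
})

test_that("degenerate category patterns are handled gracefully", {
  # a category absent from both groups carries no information
  expect_equal(smd_categorical(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 0)
  expect_equal(smd_categorical(c(0.3, 0.7, 0), c(0.4, 0.6, 0)),
               smd_categorical(c(0.3, 0.7), c(0.4, 0.6)))
  # complete separation leaves a singular covariance; fall back with warning
  expect_warning(s <- smd_categorical(c(1, 0), c(0, 1)), "singular")
  expect_equal(s, Inf)
})

test_that("perfectly matched controls give zero adjusted SMD on every covariate", {
  # one target per facility x biopsy-status combination, so each target can
  # only ever be matched to its own exact clones
  combos <- expand.grid(facility = c("I", "II", "III"),
                        biopsy = c("naive", "prev_benign", "unknown"),
                        stringsAsFactors = FALSE)
  targets <- make_exams(9, seed = 3, facility = combos$facility,
                        biopsy = combos$biopsy,
                        exam_iq = "severe", iq_source = "radiologist")
  pool <- cloned_pool(targets, 3)
  pool$exam_iq <- "optimal"
  exams <- dplyr::bind_rows(targets, pool)
  mc <- repeated_matching(targets, pool, max_rounds = 2, seed = 4)
  expect_equal(mc$rounds_completed, 2)
  bt <- suppressWarnings(balance_table(exams, mc))
  adj <- dplyr::filter(bt, comparison == "adjusted")
  expect_true(all(abs(adj$smd[!is.na(adj$smd)]) < 1e-10))
  expect_true(all(adj$balanced[!is.na(adj$smd)]))
})

test_that("a confounded unmatched pool shows at least one |SMD| >= 0.10", {
  targets <- make_exams(150, seed = 6, age = rnorm(150, 72, 8),
                        facility = sample(c("I", "II"), 150, TRUE, c(0.2, 0.8)),
                        exam_iq = "severe", iq_source = "radiologist")
  # clones keep one matching round feasible; the confounded bulk of the
  # pool shifts the unadjusted comparison
  bulk <- make_exams(600, seed = 7, prefix = "C", age = rnorm(600, 64, 8),
                     facility = sample(c("I", "II"), 600, TRUE, c(0.7, 0.3)),
                     exam_iq = "optimal", iq_source = "model")
  pool <- dplyr::bind_rows(cloned_pool(targets, 1), bulk)
  pool$exam_iq <- "optimal"
  mc <- repeated_matching(targets, pool, max_rounds = 1, seed = 8)
  expect_equal(mc$rounds_completed, 1)
  bt <- balance_table(dplyr::bind_rows(targets, pool), mc)
  unadj <- dplyr::filter(bt, comparison == "unadjusted")
  expect_true(any(abs(unadj$smd) >= 0.10, na.rm = TRUE))
})

test_that("balance_table rejects empty groups", {
  targets <- make_exams(3, seed = 9)
  mc <- repeated_matching(targets, make_exams(0, prefix = "C"), seed = 1)
  expect_error(balance_table(targets, mc), class = "mricdr_precondition_error")
})
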
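# Internal numerical helpers shared across modules.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with columns `estimate`, `conf_low`, `conf_high`; all
#'   `NA` when `n` is 0 (the proportion is undefined, never reported as 0).
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == length(n))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble::tibble(
    estimate = p,
    conf_low = pmax(0, centre - half),
    conf_high = pmin(1, centre + half)
  )
}

#' Katz log confidence interval for a ratio of two proportions
#'
#' Ratio of `x1/n1` to `x2/n2` with the standard log-scale normal interval:
#' `exp(log(RR) +/- z * sqrt(1/x1 - 1/n1 + 1/x2 - 1/n2))`.
#'
#' @param x1,n1 Numerator and denominator counts in the target group.
#' @param x2,n2 Numerator and denominator counts in the control group.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with `estimate`, `conf_low`, `conf_high`; `NA` when the
#'   ratio is undefined (zero counts make the variance or ratio undefined).
#' @export
katz_ratio_ci <- function(x1, n1, x2, n2, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ok <- n1 > 0 & n2 > 0 & x2 > 0
  rr <- ifelse(ok, (x1 / n1) / (x2 / n2), NA_real_)
  se_ok <- ok & x1 > 0
  se <- ifelse(se_ok, sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2), NA_real_)
  tibble::tibble(
    estimate = rr,
    conf_low = exp(log(rr) - z * se),
    conf_high = exp(log(rr) + z * se)
  )
}

# Deterministic stage sub-seed derived from one global seed, so each pipeline
# stage is individually reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.double(seed) * 7919 + match(stage, c(
    "simulate", "grade", "match", "balance", "analyze", "agreement"
  )) * 104729) %% 2147483647
}

# round half up at `digits` decimals (sign-aware); used where printed values
# are mirrored at 2 d.p.
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
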
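#' Standardized mean difference for a continuous covariate
#'
#' `(mean_t - mean_c) / sqrt((sd_t^2 + sd_c^2) / 2)` — the difference in
#' means in units of the pooled standard deviation. Sign-symmetric: swapping
#' the groups negates it.
#'
#' @param mean_t,sd_t Target-group mean and SD.
#' @param mean_c,sd_c Control-group mean and SD.
#' @return The SMD (dimensionless). Both SDs zero with equal means gives 0;
#'   both zero with different means is undefined and errors.
#' @export
#' @examples
#' smd_continuous(67.0, 10.1, 65.3, 8.2)  # 0.18 at 2 d.p.
smd_continuous <- function(mean_t, sd_t, mean_c, sd_c) {
  if (any(c(sd_t, sd_c) < 0, na.rm = TRUE)) {
    rlang::abort("standard deviations must be >= 0",
                 class = "mricdr_precondition_error")
  }
  denom <- sqrt((sd_t^2 + sd_c^2) / 2)
  out <- ifelse(denom == 0 & mean_t == mean_c, 0, (mean_t - mean_c) / denom)
  if (any(denom == 0 & mean_t != mean_c, na.rm = TRUE)) {
    rlang::abort("SMD undefined: zero variance in both groups with unequal means",
                 class = "mricdr_validation_error")
  }
  out
}

#' Standardized mean difference for a categorical covariate
#'
#' Multivariate (Mahalanobis-type) standardized difference over the first
#' k - 1 category proportions: `sqrt(d' S^-1 d)` with `d` the vector of
#' proportion differences and `S` the average of the two multinomial
#' covariance matrices. For two categories this reduces to the familiar
#' binary-proportion SMD (up to sign; the multivariate form is
#' non-negative). Categories absent from both groups are dropped before
#' inversion; if `S` is still singular the maximum pairwise binary SMD is
#' returned with a warning (`Inf` under complete separation).
#'
#' @param props_t,props_c Proportion vectors of equal length, each summing
#'   to 1.
#' @return Non-negative SMD.
#' @export
#' @examples
#' smd_categorical(c(0.454, 0.504, 0.043), c(0.531, 0.215, 0.254))  # 0.80
smd_categorical <- function(props_t, props_c) {
  if (length(props_t) != length(props_c)) {
    rlang::abort("proportion vectors must have equal length",
                 class = "mricdr_precondition_error")
  }
  # tolerance admits proportions transcribed from rounded printed tables
  if (abs(sum(props_t) - 1) > 0.02 || abs(sum(props_c) - 1) > 0.02) {
    rlang::abort("proportion vectors must each sum to 1",
                 class = "mricdr_precondition_error")
  }
  # categories absent from both groups carry no information and would make
  # the covariance singular; drop them first
  keep <- props_t > 0 | props_c > 0
  props_t <- props_t[keep]
  props_c <- props_c[keep]
  k <- length(props_t)
  if (k <= 1) return(0)
  d <- props_t[-k] - props_c[-k]
  cov_mat <- function(p) {
    p <- p[-k]
    diag(p, length(p)) - outer(p, p)
  }
  s <- (cov_mat(props_t) + cov_mat(props_c)) / 2
  inv <- tryCatch(solve(s), error = function(e) NULL)
  if (is.null(inv)) {
    rlang::warn("singular covariance; falling back to max pairwise binary SMD")
    pair <- vapply(seq_len(k), function(j) {
      v <- (props_t[j] * (1 - props_t[j]) + props_c[j] * (1 - props_c[j])) / 2
      d_j <- abs(props_t[j] - props_c[j])
      if (v == 0) {
        if (d_j == 0) 0 else Inf  # complete separation
      } else {
        d_j / sqrt(v)
      }
    }, numeric(1))
    return(max(pair))
  }
  sqrt(drop(t(d) %*% inv %*% d))
}

smd_from_data_continuous <- function(x_t, x_c) {
  smd_continuous(mean(x_t), stats::sd(x_t), mean(x_c), stats::sd(x_c))
}

smd_from_data_categorical <- function(x_t, x_c, levels_all) {
  pt <- as.numeric(table(factor(x_t, levels = levels_all))) / length(x_t)
  pc <- as.numeric(table(factor(x_c, levels = levels_all))) / length(x_c)
  smd_categorical(pt, pc)
}

summ_cont <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
summ_med <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
}
summ_cat <- function(x, levels_all) {
  tab <- table(factor(x, levels = levels_all))
  paste(sprintf("%s %d (%.1f%%)", names(tab), as.integer(tab),
                100 * as.integer(tab) / length(x)), collapse = "; ")
}

balance_one <- function(t_df, c_df, with_tests = TRUE) {
  rows <- list()
  add <- function(variable, summary_target, summary_control, smd, p = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = variable,
      summary_target = summary_target,
      summary_control = summary_control,
      smd = smd,
      p_value = p
    )
  }
  add("age", summ_cont(t_df$age), summ_cont(c_df$age),
      smd_from_data_continuous(t_df$age, c_df$age),
      if (with_tests) stats::t.test(t_df$age, c_df$age)$p.value else NA_real_)
  t_psa <- t_df$psa[!is.na(t_df$psa)]
  c_psa <- c_df$psa[!is.na(c_df$psa)]
  add("psa", summ_med(t_psa), summ_med(c_psa),
      if (length(t_psa) > 1 && length(c_psa) > 1) {
        smd_from_data_continuous(t_psa, c_psa)
      } else {
        NA_real_
      },
      if (with_tests && length(t_psa) > 0 && length(c_psa) > 0) {
        suppressWarnings(stats::wilcox.test(t_psa, c_psa)$p.value)
      } else {
        NA_real_
      })
  pm_t <- mean(is.na(t_df$psa))
  pm_c <- mean(is.na(c_df$psa))
  add("psa_missing",
      sprintf("%.1f%%", 100 * pm_t), sprintf("%.1f%%", 100 * pm_c),
      smd_categorical(c(pm_t, 1 - pm_t), c(pm_c, 1 - pm_c)))
  for (v in c("facility", "biopsy_status")) {
    lv <- if (v == "facility") facility_levels else biopsy_levels
    p <- NA_real_
    if (with_tests) {
      tab <- rbind(table(factor(t_df[[v]], levels = lv)),
                   table(factor(c_df[[v]], levels = lv)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) > 1) {
        p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
    add(v, summ_cat(t_df[[v]], lv), summ_cat(c_df[[v]], lv),
        smd_from_data_categorical(t_df[[v]], c_df[[v]], lv), p)
  }
  dplyr::bind_rows(rows)
}

#' Covariate balance table before and after matching
#'
#' Summarises the matching covariates (age, PSA with its missingness,
#' facility, biopsy status) for the target group against the full control
#' pool (unadjusted) and against the matched controls (adjusted), with one
#' standardized mean difference per covariate. |SMD| < 0.10 is flagged as
#' balanced. Descriptive p-values (Welch t, Wilcoxon rank-sum, chi-squared)
#' are companions, not the balance criterion.
#'
#' @param exams Examination tibble.
#' @param matched A `matched_cohort` from [repeated_matching()].
#' @param pool Optional pool tibble for the unadjusted columns; defaults to
#'   all `exam_iq == "optimal"` rows of `exams`.
#' @param with_tests Include descriptive p-values (default `TRUE`).
#' @return Tibble with one row per covariate and comparison
#'   (`comparison` = `"unadjusted"` / `"adjusted"`): group summaries, `smd`
#'   (2 d.p. in `smd_printed`), `balanced` flag.
#' @export
balance_table <- function(exams, matched, pool = NULL, with_tests = TRUE) {
  stopifnot(inherits(matched, "matched_cohort"))
  exams <- tibble::as_tibble(exams)
  t_df <- exams[exams$exam_id %in% matched$target_ids, ]
  m_df <- exams[exams$exam_id %in% control_ids(matched), ]
  if (nrow(t_df) == 0 || nrow(m_df) == 0) {
    rlang::abort("empty target or matched control group",
                 class = "mricdr_precondition_error")
  }
  if (is.null(pool)) {
    pool <- exams[!is.na(exams$exam_iq) & exams$exam_iq == "optimal", ]
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(balance_one(t_df, pool, with_tests), comparison = "unadjusted"),
    dplyr::mutate(balance_one(t_df, m_df, with_tests), comparison = "adjusted")
  )
  out |>
    dplyr::mutate(
      smd_printed = round_half_up(.data$smd, 2),
      balanced = abs(.data$smd) < 0.10
    ) |>
    dplyr::select("comparison", "variable", "summary_target",
                  "summary_control", "smd", "smd_printed", "balanced",
                  "p_value")
}

#' Love plot of covariate balance
#'
#' @param balance A [balance_table()] result.
#' @return A ggplot: |SMD| per covariate, unadjusted vs adjusted, with the
#'   0.10 balance threshold.
#' @export
plot_balance <- function(balance) {
  ggplot2::ggplot(
    balance,
    ggplot2::aes(x = abs(.data$smd), y = .data$variable,
                 colour = .data$comparison)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.10, linetype = "dashed") +
    ggplot2::labs(
      x = "|standardized mean difference|", y = NULL, colour = NULL,
      title = "Covariate balance before and after matching"
    ) +
    ggplot2::theme_minimal()
}
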
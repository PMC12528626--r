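#' Diagnostic metrics from examination counts
#'
#' The four population-level metrics of prostate MRI diagnostic yield, all
#' at the PI-RADS >= 3 threshold:
#' * CDR (cancer detection rate) = csPCa-detected exams / all exams,
#' * AIR (abnormal interpretation rate) = PI-RADS >= 3 exams / all exams,
#' * PPV = csPCa-detected / pathologically confirmed PI-RADS >= 3 exams,
#' * pathological confirmation rate = confirmed PI-RADS >= 3 / PI-RADS >= 3.
#'
#' On counts these satisfy exactly `CDR = AIR x PPV x confirmation rate`.
#' Components with a zero denominator are reported as `NA` (absent), never
#' as 0. Confidence intervals are Wilson score intervals.
#'
#' @param n_exams Total examinations.
#' @param n_pirads3plus Examinations with PI-RADS >= 3.
#' @param n_confirmed_pirads3plus PI-RADS >= 3 examinations with any
#'   pathological diagnosis (may be `NA` when unknown; PPV and the
#'   confirmation rate are then absent).
#' @param n_cspca_detected Examinations with csPCa and PI-RADS >= 3.
#' @param conf_level Confidence level for the Wilson intervals.
#' @return A `diag_metrics` object; see [tidy.diag_metrics()].
#' @export
#' @examples
#' diag_metrics(12947, 5790, NA, 3065)  # CDR 0.24, AIR 0.45
diag_metrics <- function(n_exams, n_pirads3plus, n_confirmed_pirads3plus,
                         n_cspca_detected, conf_level = 0.95) {
  if (!is.na(n_pirads3plus) && n_pirads3plus > n_exams ||
      !is.na(n_confirmed_pirads3plus) &&
        n_confirmed_pirads3plus > n_pirads3plus ||
      !is.na(n_cspca_detected) && n_cspca_detected > n_pirads3plus) {
    rlang::abort("inconsistent counts (numerators exceed denominators)",
                 class = "mricdr_validation_error")
  }
  ci <- function(x, n) {
    if (is.na(x) || is.na(n) || n == 0) {
      tibble::tibble(estimate = NA_real_, conf_low = NA_real_,
                     conf_high = NA_real_)
    } else {
      wilson_ci(x, n, conf_level)
    }
  }
  structure(
    list(
      n_exams = n_exams,
      n_pirads3plus = n_pirads3plus,
      n_confirmed_pirads3plus = n_confirmed_pirads3plus,
      n_cspca_detected = n_cspca_detected,
      cdr = ci(n_cspca_detected, n_exams),
      air = ci(n_pirads3plus, n_exams),
      ppv = ci(n_cspca_detected, n_confirmed_pirads3plus),
      confirmation_rate = ci(n_confirmed_pirads3plus, n_pirads3plus),
      conf_level = conf_level
    ),
    class = "diag_metrics"
  )
}

#' Compute diagnostic metrics from an examination table
#'
#' Counts the PI-RADS >= 3, confirmed and csPCa-detected examinations and
#' passes them to [diag_metrics()].
#'
#' @param exams Examination tibble (columns `pirads`, `confirmed`, `cspca`).
#' @param conf_level Confidence level.
#' @return A `diag_metrics` object.
#' @export
compute_metrics <- function(exams, conf_level = 0.95) {
  exams <- tibble::as_tibble(exams)
  if (nrow(exams) == 0) {
    rlang::abort("exams must be non-empty", class = "mricdr_precondition_error")
  }
  abn <- exams$pirads >= 3
  diag_metrics(
    n_exams = nrow(exams),
    n_pirads3plus = sum(abn),
    n_confirmed_pirads3plus = sum(abn & exams$confirmed),
    n_cspca_detected = sum(abn & exams$cspca),
    conf_level = conf_level
  )
}

#' @export
print.diag_metrics <- function(x, ...) {
  cat(sprintf("<diag_metrics> n = %d\n", x$n_exams))
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy diagnostic metrics
#'
#' @param x A `diag_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per metric (`cdr`, `air`, `ppv`,
#'   `confirmation_rate`): `estimate`, `conf_low`, `conf_high`,
#'   `numerator`, `denominator`.
#' @method tidy diag_metrics
#' @export
tidy.diag_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("cdr", "air", "ppv", "confirmation_rate"),
    estimate = c(x$cdr$estimate, x$air$estimate, x$ppv$estimate,
                 x$confirmation_rate$estimate),
    conf_low = c(x$cdr$conf_low, x$air$conf_low, x$ppv$conf_low,
                 x$confirmation_rate$conf_low),
    conf_high = c(x$cdr$conf_high, x$air$conf_high, x$ppv$conf_high,
                  x$confirmation_rate$conf_high),
    numerator = c(x$n_cspca_detected, x$n_pirads3plus, x$n_cspca_detected,
                  x$n_confirmed_pirads3plus),
    denominator = c(x$n_exams, x$n_exams, x$n_confirmed_pirads3plus,
                    x$n_pirads3plus)
  )
}

#' One-row summary of diagnostic metrics
#' @param x A `diag_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with the counts and the four point estimates.
#' @method glance diag_metrics
#' @export
glance.diag_metrics <- function(x, ...) {
  tibble::tibble(
    n_exams = x$n_exams,
    n_pirads3plus = x$n_pirads3plus,
    n_confirmed_pirads3plus = x$n_confirmed_pirads3plus,
    n_cspca_detected = x$n_cspca_detected,
    cdr = x$cdr$estimate,
    air = x$air$estimate,
    ppv = x$ppv$estimate,
    confirmation_rate = x$confirmation_rate$estimate
  )
}

#' Compare target and control diagnostic metrics
#'
#' Ratios (target / control) of CDR, AIR, PPV and the confirmation rate
#' with Katz log confidence intervals, and a Pearson chi-squared test
#' (no continuity correction) of csPCa detection between the groups on the
#' detected / not-detected 2x2 table. On the unrounded counts the ratios
#' satisfy `cdr_ratio = air_ratio x ppv_ratio x confirmation_ratio` exactly.
#' A zero control component leaves the affected ratio absent with a warning.
#'
#' @param target,control `diag_metrics` objects.
#' @param conf_level Confidence level for the ratio intervals.
#' @return A `metric_ratios` object; see [tidy.metric_ratios()].
#' @export
compare_groups <- function(target, control, conf_level = 0.95) {
  stopifnot(inherits(target, "diag_metrics"), inherits(control, "diag_metrics"))
  ratio <- function(x1, n1, x2, n2) {
    if (any(is.na(c(x1, n1, x2, n2))) || n1 == 0 || n2 == 0 || x2 == 0) {
      if (!any(is.na(c(x1, n1, x2, n2)))) {
        rlang::warn("zero control component; ratio reported as absent")
      }
      tibble::tibble(estimate = NA_real_, conf_low = NA_real_,
                     conf_high = NA_real_)
    } else {
      katz_ratio_ci(x1, n1, x2, n2, conf_level)
    }
  }
  tab <- rbind(
    c(target$n_cspca_detected, target$n_exams - target$n_cspca_detected),
    c(control$n_cspca_detected, control$n_exams - control$n_cspca_detected)
  )
  chi2 <- if (any(colSums(tab) == 0)) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  structure(
    list(
      cdr_ratio = ratio(target$n_cspca_detected, target$n_exams,
                        control$n_cspca_detected, control$n_exams),
      air_ratio = ratio(target$n_pirads3plus, target$n_exams,
                        control$n_pirads3plus, control$n_exams),
      ppv_ratio = ratio(target$n_cspca_detected, target$n_confirmed_pirads3plus,
                        control$n_cspca_detected, control$n_confirmed_pirads3plus),
      confirmation_ratio = ratio(
        target$n_confirmed_pirads3plus, target$n_pirads3plus,
        control$n_confirmed_pirads3plus, control$n_pirads3plus
      ),
      chi2_statistic = unname(chi2$statistic),
      chi2_p = chi2$p.value,
      target = target,
      control = control
    ),
    class = "metric_ratios"
  )
}

#' @export
print.metric_ratios <- function(x, ...) {
  cat("<metric_ratios>\n")
  print(generics::tidy(x))
  cat(sprintf("chi-squared p = %.3g\n", x$chi2_p))
  invisible(x)
}

#' Tidy metric ratios
#'
#' @param x A `metric_ratios` object.
#' @param ... Unused.
#' @return Tibble with one row per ratio: `estimate`, `conf_low`,
#'   `conf_high`.
#' @method tidy metric_ratios
#' @export
tidy.metric_ratios <- function(x, ...) {
  tibble::tibble(
    ratio = c("cdr_ratio", "air_ratio", "ppv_ratio", "confirmation_ratio"),
    estimate = c(x$cdr_ratio$estimate, x$air_ratio$estimate,
                 x$ppv_ratio$estimate, x$confirmation_ratio$estimate),
    conf_low = c(x$cdr_ratio$conf_low, x$air_ratio$conf_low,
                 x$ppv_ratio$conf_low, x$confirmation_ratio$conf_low),
    conf_high = c(x$cdr_ratio$conf_high, x$air_ratio$conf_high,
                  x$ppv_ratio$conf_high, x$confirmation_ratio$conf_high)
  )
}

#' One-row summary of a group comparison
#' @param x A `metric_ratios` object.
#' @param ... Unused.
#' @return One-row tibble with the four ratios and the chi-squared result.
#' @method glance metric_ratios
#' @export
glance.metric_ratios <- function(x, ...) {
  tibble::tibble(
    cdr_ratio = x$cdr_ratio$estimate,
    air_ratio = x$air_ratio$estimate,
    ppv_ratio = x$ppv_ratio$estimate,
    confirmation_ratio = x$confirmation_ratio$estimate,
    chi2_statistic = x$chi2_statistic,
    chi2_p = x$chi2_p
  )
}

#' Zone-restricted subgroup of examinations
#'
#' The peripheral-zone (transition-zone) subgroup excludes examinations
#' with proven csPCa whose dominant lesion is in the other zone; all other
#' examinations are retained. A csPCa examination with `dominant_zone`
#' `"none"` is retained with a warning.
#'
#' @param exams Examination tibble.
#' @param zone `"PZ"` or `"TZ"`.
#' @return The filtered tibble.
#' @export
zone_subgroup <- function(exams, zone = c("PZ", "TZ")) {
  zone <- match.arg(zone)
  exams <- tibble::as_tibble(exams)
  odd <- exams$cspca & exams$dominant_zone == "none"
  if (any(odd)) {
    rlang::warn(sprintf(
      "%d csPCa examination(s) without a dominant zone retained in the subgroup",
      sum(odd)
    ))
  }
  other <- setdiff(c("PZ", "TZ"), zone)
  dplyr::filter(exams, !(.data$cspca & .data$dominant_zone == other))
}

#' Association between binarized IQ and a patient factor
#'
#' Cross-tabulates poor (severe-moderate) vs acceptable (mild-optimal) IQ
#' against a factor. Categorical factors get a Pearson chi-squared test;
#' continuous factors a Welch t-test (`test = "t"`) or Wilcoxon rank-sum
#' (`test = "wilcox"`, for skewed variables such as PSA). A constant factor
#' is flagged: the test is undefined and `p_value` is `NA`.
#'
#' @param exams Examination tibble with `exam_iq` assigned.
#' @param factor_var Column name of the factor.
#' @param test `"auto"` (chi-squared for character/factor, t otherwise),
#'   `"chisq"`, `"t"` or `"wilcox"`.
#' @return A `factor_assoc` list: `factor_var`, `test`, `table` (counts or
#'   group summaries), `statistic`, `p_value`, `defined`.
#' @export
factor_association <- function(exams, factor_var,
                               test = c("auto", "chisq", "t", "wilcox")) {
  test <- match.arg(test)
  exams <- tibble::as_tibble(exams)
  if (!factor_var %in% names(exams)) {
    rlang::abort(sprintf("no column '%s' in exams", factor_var),
                 class = "mricdr_schema_error")
  }
  iq_bin <- binarize_iq(exams$exam_iq)
  x <- exams[[factor_var]]
  keep <- !is.na(iq_bin) & !is.na(x)
  iq_bin <- iq_bin[keep]
  x <- x[keep]
  if (length(unique(iq_bin)) < 2) {
    rlang::abort("both IQ strata must be non-empty",
                 class = "mricdr_df_error")
  }
  if (test == "auto") {
    test <- if (is.character(x) || is.factor(x) || is.logical(x)) "chisq" else "t"
  }
  if (test == "chisq") {
    tab <- table(iq_bin, x)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      return(structure(
        list(factor_var = factor_var, test = test, table = tab,
             statistic = NA_real_, p_value = NA_real_, defined = FALSE),
        class = "factor_assoc"
      ))
    }
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- list(table = tab, statistic = unname(res$statistic),
                p_value = res$p.value, defined = TRUE)
  } else {
    summ <- tibble::tibble(
      iq = levels(iq_bin),
      n = as.integer(table(iq_bin)),
      mean = tapply(x, iq_bin, mean),
      sd = tapply(x, iq_bin, stats::sd),
      median = tapply(x, iq_bin, stats::median)
    )
    if (stats::sd(x) == 0) {
      out <- list(table = summ, statistic = NA_real_, p_value = NA_real_,
                  defined = FALSE)
    } else if (test == "t") {
      res <- stats::t.test(x ~ iq_bin)
      out <- list(table = summ, statistic = unname(res$statistic),
                  p_value = res$p.value, defined = TRUE)
    } else {
      res <- suppressWarnings(stats::wilcox.test(x ~ iq_bin))
      out <- list(table = summ, statistic = unname(res$statistic),
                  p_value = res$p.value, defined = TRUE)
    }
  }
  structure(c(list(factor_var = factor_var, test = test), out),
            class = "factor_assoc")
}

#' @export
print.factor_assoc <- function(x, ...) {
  cat(sprintf("<factor_assoc> %s (%s test)\n", x$factor_var, x$test))
  print(x$table)
  if (x$defined) {
    cat(sprintf("statistic = %.4g, p = %.3g\n", x$statistic, x$p_value))
  } else {
    cat("test undefined (degenerate factor)\n")
  }
  invisible(x)
}

#' Tidy a factor-association result
#' @param x A `factor_assoc` object.
#' @param ... Unused.
#' @return One-row tibble: `factor_var`, `test`, `statistic`, `p_value`,
#'   `defined`.
#' @method tidy factor_assoc
#' @export
tidy.factor_assoc <- function(x, ...) {
  tibble::tibble(
    factor_var = x$factor_var, test = x$test,
    statistic = x$statistic, p_value = x$p_value, defined = x$defined
  )
}

#' Forest-style plot of metric ratios across severity groups
#'
#' @param ratios Named list of `metric_ratios` (e.g. per severity category,
#'   as produced by [run_pipeline()]).
#' @return A ggplot of ratio point estimates with confidence intervals, a
#'   reference line at 1.
#' @export
plot_metric_ratios <- function(ratios) {
  df <- purrr::imap_dfr(ratios, function(r, nm) {
    dplyr::mutate(generics::tidy(r), group = nm)
  })
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$ratio, y = .data$estimate, colour = .data$group)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "target / control ratio", colour = "severity",
      title = "Diagnostic performance ratios by artifact severity"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metric_ratios
#' @param object A `metric_ratios` object.
#' @param ... Unused.
#' @method autoplot metric_ratios
#' @export
autoplot.metric_ratios <- function(object, ...) {
  plot_metric_ratios(list(comparison = object))
}
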
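#' Ordinal image-quality categories
#'
#' Severity of gas-induced susceptibility artifact on low b-value DWI is
#' graded by the proportion of the prostate obscured: `optimal` (0%),
#' `mild` (10%), `moderate` (20%) and `severe` (>= 30%). The scale is a
#' total order `optimal < mild < moderate < severe`.
#'
#' @return `iq_levels()` returns the four category names in increasing
#'   severity order.
#' @export
#' @examples
#' iq_levels()
#' as_iq(c("severe", "optimal"))
iq_levels <- function() {
  c("optimal", "mild", "moderate", "severe")
}

#' Coerce to an ordered IQ factor
#'
#' @param x A character, factor, or integer vector. Integers are ordinal
#'   codes 0 = optimal .. 3 = severe.
#' @return An ordered factor with levels `iq_levels()`; `NA` is preserved.
#' @export
as_iq <- function(x) {
  lv <- iq_levels()
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% 0:3)
    if (any(bad)) {
      rlang::abort(
        sprintf("IQ ordinal codes must be 0..3; offending values: %s",
                paste(unique(x[bad]), collapse = ", ")),
        class = "mricdr_validation_error"
      )
    }
    x <- lv[x + 1L]
  }
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad)) {
    rlang::abort(
      sprintf("Unknown IQ category: %s", paste(unique(x[bad]), collapse = ", ")),
      class = "mricdr_validation_error"
    )
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' @describeIn as_iq Ordinal code (0 = optimal .. 3 = severe) of a category.
#' @export
iq_code <- function(x) {
  as.integer(as_iq(x)) - 1L
}
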
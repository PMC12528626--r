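Package: mricdr
Title: Matched-Cohort Cancer Detection Rate Analysis for Prostate MRI Image Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the clinical impact of diffusion-weighted
    imaging (DWI) artifacts on prostate MRI diagnostic performance. Provides
    an ordinal image-quality (IQ) rubric based on the obscured-prostate
    proportion, multi-rater consensus and exam-level IQ selection, a repeated
    coarsened exact matching engine for constructing artifact-severity
    case-control cohorts, standardized mean difference balance diagnostics,
    cancer detection rate (CDR) decomposition into abnormal interpretation
    rate, positive predictive value and pathological confirmation rate with
    ratio confidence intervals, inter-rater agreement statistics (multi-rater
    generalized kappa, quadratic weighted kappa), and a synthetic cohort
    generator with configurable confounding and IQ-dependent detection for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
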
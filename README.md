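# mricdr

Matched-cohort cancer detection rate analysis for prostate MRI image
quality.

## What problem this solves

Gas in the rectum degrades diffusion-weighted prostate MRI (DWI) with
susceptibility artifacts, and DWI is the sequence that drives PI-RADS
scoring for clinically significant prostate cancer (csPCa, Grade
group ≥ 2). Quantifying whether — and through which mechanism — that
degradation costs cancer detections is a confounded observational
comparison: poor-quality examinations cluster by facility, patient age,
PSA availability and biopsy history. `mricdr` is for imaging researchers
and biostatisticians who need that comparison done carefully and
reproducibly:

* **IQ grading** — an ordinal rubric on the obscured-prostate proportion
  (0% → optimal, 10% → mild, 20% → moderate, ≥ 30% → severe), median
  consensus over rater panels with explicit adjudication policy,
  radiologist-over-model reconciliation, best-series examination-level IQ.
* **Repeated coarsened exact matching** — per severity group, iterative
  all-or-nothing 1:1 rounds against an optimal-IQ pool, exact on facility
  and biopsy status, quantile-coarsened on age and PSA (6-bin narrow tier
  with a 3-bin wide fallback, missing-PSA bin), no control reuse within a
  group; the achieved 1:k ratio equals the completed rounds.
* **Balance diagnostics** — standardized mean differences before/after
  matching (Mahalanobis-type SMD for multi-level factors), |SMD| < 0.10
  flagged as balanced, love plots.
* **CDR decomposition** — at the examination level with PI-RADS ≥ 3 as the
  abnormal threshold:

  ```
  CDR = AIR × PPV × pathological confirmation rate
  ```

  exact on counts, with Wilson intervals, Katz log ratio intervals, and a
  Pearson chi-squared comparison; zone-restricted (PZ/TZ) subgroups and
  binarized-IQ factor associations.
* **Agreement statistics** — multi-rater generalized (Fleiss) kappa,
  quadratic weighted kappa, Landis–Koch labels, confusion matrices.
* **Synthetic cohorts** — a generator with planted confounding and
  IQ-dependent detection so every stage of the pipeline is testable
  end-to-end, including recovery of planted CDR-ratio effects.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()`
methods on fitted objects, `autoplot()`/`plot_*()` figures, and a single
`run_pipeline()` orchestrator with a reproducibility manifest.

## Worked example

Diagnostic metrics straight from examination counts — 12,947 examinations,
5,790 read as PI-RADS ≥ 3, 3,065 csPCa detections:

```r
library(mricdr)
tidy(diag_metrics(12947, 5790, NA, 3065))
#> # A tibble: 4 × 6
#>   metric            estimate conf_low conf_high numerator denominator
#>   <chr>                <dbl>    <dbl>     <dbl>     <dbl>       <dbl>
#> 1 cdr                  0.237    0.229     0.244      3065       12947
#> 2 air                  0.447    0.439     0.456      5790       12947
#> 3 ppv                 NA       NA        NA          3065          NA
#> 4 confirmation_rate   NA       NA        NA            NA        5790
```

A CDR of 0.24 with an AIR of 0.45: a quarter of all examinations end in a
detected csPCa, and the confirmation-rate/PPV components stay absent
(`NA`) rather than silently zero when the pathology count is unknown.

The full pipeline on a synthetic cohort — simulate, grade, match, check
balance, compare:

```r
report <- run_pipeline(run_config(
  seed = 42,
  sim = sim_config(n_exams = 8000),
  max_rounds = 5,
  zones = "PZ"
))
report$log
#>   stage    message
#> 1 simulate generated 8000 exams, 8477 series
#> 2 grade    exam-level IQ: optimal 4240, mild 2923, moderate 771, severe 66
#> 3 match    mild: 140 targets, 700 controls (1:5)
#> 4 match    moderate: 124 targets, 620 controls (1:5)
#> 5 match    severe: 66 targets, 330 controls (1:5)

tidy(report)[9:12, 1:6]
#>   severity ratio              estimate conf_low conf_high chi2_p
#> 9  severe  cdr_ratio             0.778    0.473     1.28   0.307
#> 10 severe  air_ratio             1        0.768     1.30   0.307
#> 11 severe  ppv_ratio             0.778    0.531     1.14   0.307
#> 12 severe  confirmation_ratio    1        0.838     1.19   0.307
```

66 severe examinations were matched 1:5 to optimal-IQ controls; their CDR
ratio of 0.78 (95% CI 0.47–1.28, χ² p = 0.31) decomposes into an unchanged
abnormal-interpretation rate and confirmation rate and a reduced PPV — at
this sample size the planted severity gradient is visible but not
significant, exactly the small-target-group regime the method is built
for. Balance after matching:

```r
dplyr::filter(report$balance$severe, comparison == "adjusted")[, c(2, 6, 7)]
#>   variable      smd_printed balanced
#> 1 age                 -0.01 TRUE
#> 2 psa                  0.05 TRUE
#> 3 psa_missing          0    TRUE
#> 4 facility            0     TRUE
#> 5 biopsy_status       0     TRUE
```

`plot_balance(report$balance$severe)` and
`plot_metric_ratios(lapply(report$metrics, \(m) m$ratios))` draw the love
plot and the forest-style ratio panel. See the methods vignette
(`vignettes/matched-cdr-analysis.Rmd`) for the model, the matching
procedure, generator assumptions and numerical edge cases.

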
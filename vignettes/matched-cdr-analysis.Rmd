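---
title: "Matched-cohort CDR analysis for prostate MRI image quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-cohort CDR analysis for prostate MRI image quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mricdr)
library(dplyr)
```

## The problem

Rectal gas produces susceptibility artifacts on diffusion-weighted prostate
MRI (DWI), the sequence most sensitive to clinically significant prostate
cancer (csPCa, Grade group >= 2). Whether those artifacts actually reduce
the cancer yield of MRI is a causal question about observational data:
examinations with poor image quality (IQ) differ systematically from clean
ones (facility protocols, patient mix, PSA availability), so a naive
comparison of detection rates is confounded.

`mricdr` implements the analytic machinery for answering that question at
the examination level:

1. an ordinal IQ rubric on the obscured-prostate proportion
   (0% optimal, 10% mild, 20% moderate, >= 30% severe), with multi-rater
   median consensus and best-series exam-level selection;
2. a repeated coarsened exact matching (CEM) engine that builds, for each
   artifact-severity target group, a control group of optimal-IQ
   examinations balanced on age, PSA, facility and pre-MRI biopsy status;
3. standardized mean difference (SMD) balance diagnostics;
4. the cancer detection rate (CDR) and its exact decomposition
   CDR = AIR x PPV x pathological confirmation rate, with confidence
   intervals, ratios and a chi-squared group comparison;
5. inter-rater agreement statistics (multi-rater generalized kappa,
   quadratic weighted kappa, Landis-Koch labels);
6. a synthetic cohort generator so that every stage — and the pipeline as
   a whole — is testable without patient data.

## The metrics and their decomposition

With all quantities counted per examination at the PI-RADS >= 3 threshold:

* **AIR** (abnormal interpretation rate) = #(PI-RADS >= 3) / #exams;
* **confirmation rate** = #(pathology obtained ∩ PI-RADS >= 3) / #(PI-RADS >= 3);
* **PPV** = #(csPCa ∩ PI-RADS >= 3) / #(pathology obtained ∩ PI-RADS >= 3);
* **CDR** = #(csPCa ∩ PI-RADS >= 3) / #exams.

On raw counts the product identity `CDR = AIR x PPV x confirmation rate`
holds exactly, and so does its ratio version between two groups. The
decomposition attributes a CDR shift to reading behaviour (AIR), work-up
intensity (confirmation rate) or diagnostic precision (PPV). Components
with a zero denominator are reported as absent (`NA`), never as zero.

Interval choices: Wilson score intervals for proportions, the Katz log
method for ratios of proportions, and a Pearson chi-squared test without
continuity correction on the detected/not-detected 2x2 table. These are
documented defaults, not claims about what any particular study used; both
are standard and swappable. The matched-cohort chi-squared treats
observations as independent — a deliberate reproduction of common practice
for this design, not an endorsement; a paired analysis would need the
pair structure that 1:k round-matching only partially provides.

## The matching procedure

Targets are the radiologist-graded mild, moderate and severe examinations;
the pool is every optimal examination (radiologist- or model-graded).
Matching covariates are facility and pre-MRI biopsy status (never
coarsened) plus age and PSA, each coarsened twice: into 6 quantile bins
(narrow) and 3 quantile bins (wide), with a dedicated bin for missing PSA
at both levels. Quantiles are computed once per category run on the union
of targets and current pool, so bins are not defined by one side alone.

Rounds are all-or-nothing 1:1 passes: targets are visited in random order,
each takes an unused control agreeing exactly on the narrow key, falling
back to the wide key, chosen uniformly among candidates. If any target
finds no candidate the round is discarded; otherwise its controls leave
the pool for good. The achieved control:target ratio equals the number of
completed rounds. Because visiting order can make a feasible round fail,
a failed round is retried with fresh random orders (default 10 attempts)
before matching stops — both the retry count and every random draw are
seed-controlled, so runs reproduce exactly.

Two readings of the published bin description are possible (two
coarsening tiers per covariate, or age at 3 bins and PSA at 6 with no
tiers); we implement the two-tier fallback for both covariates, which is
the reading under which the "narrower bins first, wider on failure"
sentence is meaningful. Since the 3-bin cut points are a subset of the
6-bin cut points (both are quantiles at multiples of 1/6), narrow bins
refine wide bins, and a round is feasible exactly when every wide-key
class contains at least as many pool members as targets — the counting
oracle the test suite checks the engine against.

## Balance diagnostics

`balance_table()` reports each covariate for the target group against the
full pool (unadjusted) and the matched controls (adjusted). Continuous
covariates use `(m_t - m_c) / sqrt((s_t^2 + s_c^2)/2)`; categorical
covariates use the multivariate Mahalanobis-type SMD
`sqrt(d' S^-1 d)` over the first k-1 proportions with S the average
multinomial covariance — this reproduces published single-number SMDs for
three-level factors such as facility, which is why it was chosen. PSA is
summarised as median [IQR] with its SMD computed on non-missing values,
and missingness itself gets a binary SMD row. |SMD| < 0.10 is flagged as
balanced. The companion p-values (Welch t, Wilcoxon rank-sum, chi-squared)
are descriptive only.

## The synthetic cohort generator

`generate_cohort()` draws, per examination: facility (probabilities
0.531/0.215/0.254), age ~ Normal(65.5, 8.4) truncated to [30, 95], PSA
log-normal (median 6.3 ng/mL, log-SD 0.5) with 17.7% missingness, biopsy
status (0.308/0.302/0.390), and a planted exam-level IQ category
(0.528/0.366/0.098/0.008). Disease risk is logistic in standardized age
and log-PSA with facility offsets around a base prevalence of 0.25 — the
simplest confounding structure the matching must undo; the default
coefficient magnitudes (0.35 per SD age, 0.6 per SD log-PSA, facility
offsets ±0.1) are documented choices, not estimates from any study.

Detection: a csPCa examination receives PI-RADS >= 3 with probability
`detection_sensitivity_by_iq[category]` (defaults 0.95/0.95/0.93/0.87,
a modest severity gradient); a non-csPCa examination with the
IQ-independent false-positive rate 0.28. PI-RADS >= 3 is then drawn from
{3,4,5} for detected cancers and {3,4} for false positives; only the >= 3
threshold matters to any metric. Proven csPCa is the disease draw itself
and is always pathologically confirmed — the one-year pathology window is
assumed to ascertain every csPCa — while non-csPCa examinations are
confirmed with probability 0.6 given PI-RADS >= 3 (work-up) or 0.1 given
PI-RADS 1-2 (systematic biopsy). Two consequences worth knowing: the
observed csPCa fraction equals the configured prevalence under neutral
confounders, and a planted multiplicative deficit `m` in severe-IQ
sensitivity shifts the severe-vs-optimal CDR ratio by exactly `m` in
expectation, which is what the recovery tests exploit.

Series structure: 1-3 DWI series per exam (0.95/0.04/0.01); the first
series carries the planted category and extras are drawn equal-or-worse,
so the best series reproduces the exam category. Severe series get an
obscured proportion >= 30% concentrated in 30-40% (78% of draws).
Radiologist review — which defines the target groups — covers all
model-predicted severe series, 16% of moderate predictions, and a 5%
random sample of everything (the reader-study analogue); reviewed series
carry an `obscured_pct`, unreviewed ones only the model category. The
generator's model predictions are noise-free; rater disagreement is
studied separately through `generate_ratings()` and a confusion matrix.

What the generator does **not** emulate: longitudinal repeat examinations
per patient, reader-specific bias, facility-specific PSA assay or protocol
drift, lesion-level (as opposed to exam-level) outcomes, and any
image-domain phenomenon. Passing tests therefore validate the analytic
machinery — grading, matching, balance, decomposition, recovery of planted
effects — not claims about real patients.

## Numerical and degenerate-input choices

* Ordinal medians of even rater panels can fall between categories; the
  default resolves to the worse category and flags the item
  (`adjudication_needed`), mirroring a conservative human adjudication;
  `"better"` and `"error"` policies are available.
* Quantile bins use type-7 quantiles; a covariate with too few distinct
  values degenerates to fewer bins with a warning; all-missing or
  constant covariates collapse to a single bin.
* SMD with zero variance in both groups is 0 when means agree and an
  error otherwise; a singular multinomial covariance falls back to the
  maximum pairwise binary SMD with a warning.
* Kappa statistics are undefined (returned as `NA`, with a warning) when
  chance agreement is 1; Landis-Koch labels round half-up to two decimals
  before banding, so 0.805 is "almost perfect" and 0.804 "substantial".
* Exams with multiple MRI dates per patient are not modelled; pathology
  linkage is abstracted into the boolean `confirmed`, a deliberate
  simplification users should be aware of when mapping real data in.

## Worked example

```{r pipeline}
report <- run_pipeline(run_config(
  seed = 42,
  sim = sim_config(n_exams = 8000),
  max_rounds = 5,
  zones = "PZ"
))
tidy(report)
```

```{r balance}
report$balance$severe |>
  filter(comparison == "adjusted") |>
  select(variable, smd_printed, balanced)
```

All adjusted |SMD| sit below 0.10: the matched controls are balanced, so
the remaining CDR-ratio spread reflects the planted detection gradient
plus sampling noise.

```{r agreement}
truth <- sample(iq_levels(), 200, replace = TRUE,
                prob = c(0.6, 0.25, 0.1, 0.05))
noisy <- 0.7 * diag(4) + 0.1 *
  (abs(outer(1:4, 1:4, "-")) == 1) / rowSums(abs(outer(1:4, 1:4, "-")) == 1) * 1.2
noisy <- noisy / rowSums(noisy)
ratings <- generate_ratings(truth, n_raters = 7, confusion = noisy, seed = 1)
generalized_kappa(ratings)
```

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use cohorts of 2,000 to
20,000 examinations and 15-30 replicates for the coverage checks. These
sizes give severe target groups of roughly 100-160 examinations — the
order of magnitude at which a rare-severity matched analysis is realistic —
while keeping every run reproducible from a single seed.

## Known limitations

* All-or-nothing rounds mean one unmatchable target ends matching for the
  whole category; with small pools this is abrupt (by design — it is what
  keeps completed rounds exactly 1:1).
* Ratio confidence intervals ignore the matched-pair correlation, as does
  the chi-squared comparison.
* The generator's review mechanism is a two-parameter sketch of a
  targeted + random human review; real review processes are richer.
* Multi-category SMD has no universally agreed definition; ours is one
  defensible, reproducible choice.
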
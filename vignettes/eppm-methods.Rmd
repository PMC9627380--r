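---
title: "Methods: the EPPM score, its screening pipeline, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the EPPM score, its screening pipeline, and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eppm)
```

## The model

The EPPM is a point-based prognostic score for traumatic brain injury.
Seven predictors available at admission — age, dominant damaged lobe,
Glasgow Coma Scale (GCS), APOE ε4 carrier status, serum C-reactive
protein (CRP), serum interleukin-8 (IL-8), and Marshall CT class — are
each mapped to an integer number of points by fixed grading rules
(`default_rules()`), and the patient's score is the plain sum, ranging
from 10 (least severe bin everywhere) to 33 (most severe everywhere).
A poor early (14-day) prognosis is predicted when the total strictly
exceeds a decision threshold, 23.5 by default, so integer totals of 24
and above classify as poor.

Point scores of this kind trade statistical efficiency for bedside
auditability: every prediction decomposes into seven visible
contributions, which is why the rules ship as a data file rather than
code — an alternative scheme can be evaluated by editing YAML, with no
change to the software.

### Boundary conventions

The grading bins abut at several edges (CRP "10–15" against "≥15", IL-8
"10–20" against "≥20", the age bands). The implementation treats every
numeric bin as half-open `[min, max)` with the top bin closed at the
domain maximum, so a value on an abutting edge always takes the points of
the more severe category: CRP 15 scores 5, IL-8 20 scores 4, age 60
scores 6. This convention is deterministic, makes the bins provably
exhaustive and non-overlapping (the test suite sweeps a fine grid over
every domain), and agrees with the worked example in which CRP 14.2
scores 3. Age is interpreted in whole years, so 45 scores 4 and 46
scores 5.

### Classification at the threshold

"Poor" requires a total *strictly greater* than the threshold. With the
non-integer default 23.5 the rule is unambiguous; it matters only for
user-supplied integer thresholds, where a patient exactly at the
threshold stays "good". The threshold must lie strictly inside the
achievable range [10, 33] so that both classes are reachable.

### The six- versus seven-predictor total

The published worked example sums six predictors (age, damaged lobe, ε4,
CRP, IL-8, Marshall = 19) even though the example patient's GCS of 8
carries 6 points. The package treats the six-predictor sum as a
reproduction surface only — `score_cohort()` accepts a `predictors`
argument — and includes GCS in the default set, because the grading
table has a GCS row and GCS is listed among the model's incorporated
predictors. The seven-predictor total for that patient is 25.

## The screening pipeline

`screen_predictors()` reproduces the two-stage predictor screen:

1. **Univariate.** Continuous analytes are compared between outcome
   groups with Student's t-test when both groups pass a Shapiro–Wilk
   normality gate at α = 0.05, and with the Mann–Whitney test otherwise.
   A variance-homogeneity check (Brown–Forsythe: Levene's test with
   median centring) decides between the pooled and the Welch t-statistic;
   normal-but-heteroscedastic data stay on the t branch rather than
   falling back to ranks, the least destructive reading of "a
   homogeneity of variance test was carried out". Categorical and binned
   predictors (age and GCS are binned exactly as the grading rules bin
   them) use the Pearson chi-square without continuity correction —
   matching the uncorrected statistic conventionally reported by the
   standard clinical statistics packages — falling back to Fisher's
   exact test when a 2×2 table has an expected count below 5, and
   keeping chi-square with a warning for larger sparse tables. No
   multiple-testing correction is applied across the screen, matching
   the source procedure.

2. **Multivariate.** All univariate-selected candidates enter one
   maximum-likelihood logistic regression of poor outcome. Multi-level
   predictors are coded as equally spaced integers in severity order
   (`encode_ordinal()`): age bands 1–3, GCS bands 1–3 (13–15 is 1),
   damaged lobe parietal < occipital < temporal < frontal, Marshall I–VI
   as 1–6, CRP and IL-8 by their grading bins. A single published odds
   ratio per multi-level predictor is only consistent with such a
   one-coefficient trend coding; whether the original analysis used
   ordinal or dummy coding is not stated, so this is a design choice of
   the package. Odds ratios are reported with Wald 95% intervals and
   p-values; perfect separation and non-convergence raise explicit
   errors instead of returning astronomically large estimates.

Predictors with multivariate p < α (default 0.05 throughout) are the
"independent risk factors" the pipeline selects.

## Evaluation

`roc_curve()` sweeps thresholds at the midpoints between consecutive
distinct scores plus sentinels half a point below the minimum and above
the maximum, so the (sensitivity 1, specificity 0) and (0, 1) endpoints
always exist. The AUC is the trapezoidal area, which for this
construction equals the tie-adjusted concordance probability (a tied
poor/good score pair counts one half) — an identity the test suite
verifies against exhaustive pair counting to 1e-12. The AUC's 95%
interval uses the Hanley–McNeil standard error with a normal
approximation, a standard closed form chosen because the published
intervals name no method. `youden_threshold()` maximises
J = sensitivity + specificity − 1, breaking ties toward higher
specificity and then the higher threshold (ties occur routinely with
integer scores). `evaluate_model()` freezes the threshold on the
training set — Youden-optimal if none is supplied — before computing
validation and testing metrics, so no set's metrics depend on
re-optimising against its own labels.

## The synthetic cohort generator

No patient-level data were published, so `generate_cohort()` emulates a
cohort from the printed summary tables: outcome drawn Bernoulli(78/168),
each categorical predictor drawn from its outcome-conditional category
frequencies (the printed per-outcome counts), age and GCS drawn
uniformly inside the sampled band (15–45 / 46–59 / 60–75 and 3–8 / 9–12 /
13–15), and serum analytes drawn from per-outcome normal distributions
truncated at zero. Sex, injury mechanism and the comorbidity flags carry
no outcome signal and are drawn from the cohort marginals, giving the
screening pipeline true negatives to reject.

Three deliberate choices:

- **Conditional independence.** Predictors are independent given the
  outcome, because only per-outcome marginals are published; no joint
  structure is recoverable. Consequently the generator reproduces each
  marginal association with outcome but not predictor–predictor
  correlations (e.g. GCS and Marshall class are more correlated in real
  TBI cohorts than here). Pipeline results on synthetic cohorts
  therefore validate the software and the statistical procedures, not
  the clinical performance of the score on real patients.
- **Which analytes carry signal.** Only CRP and IL-8 are drawn
  conditionally on outcome. The source tables print per-group means for
  seventeen further analytes while reporting them as non-discriminating
  (p > 0.05); taking those mean pairs literally would make creatinine a
  stronger predictor than CRP, contradicting the reported screening
  outcome. The pooled-mixture draw (an independent phantom outcome picks
  the component) keeps each such analyte's printed marginal distribution
  while injecting no prognostic signal. The same mechanism drives
  `generate_null_cohort()`, where *every* predictor is pooled and the
  score's AUC is 0.5 in expectation.
- **Moment-corrected truncation.** Truncating a normal at zero by
  resampling inflates its mean — for CRP (14.20 ± 5.73) by about
  0.11 mg/L, which is two standard errors at the generator's own
  n = 10,000 recovery tolerance. The sampler therefore solves for the
  latent location whose zero-truncated mean equals the configured mean;
  the residual SD distortion is second-order and left uncorrected (for
  heavily truncated analytes such as procalcitonin the realized SD is
  slightly below the configured one).

All parameters live in `inst/extdata/cohort_defaults.yaml` as counts and
mean/SD pairs, the single in-package source of the published numbers.
One seeded generator drives a cohort; the seed and a configuration hash
are stamped on the result for provenance, and the caller's RNG state is
untouched.

A known tension: the published binned CRP/IL-8 counts cannot be matched
exactly by any normal model that also matches the published means and
SDs (the printed IL-8 bin counts even place zero patients below
10 pg/mL in both groups). The normal summaries are taken as the
generative source; `summarize_cohort()` reports the implied binned
frequencies so the discrepancy is visible rather than hidden.

## Problem sizes and numerical tolerances

The test suite works at sizes where the statistical properties are
sharp but cheap: AUC/concordance equivalence on 1,000 random instances
of up to 50 patients at 1e-12; type-I-error calibration of both
univariate branches with 1,000 null replicates against a ±2 Monte-Carlo-SE
band around 0.05; power at the published CRP effect (group sizes 78/90)
over 200 replicates; logistic parameter recovery on one n = 5,000 cohort
(every odds ratio within 10% of truth) with Wald coverage assessed over
200 replicates at n = 1,500; generator moment recovery at n = 10,000
within 3 SEs; and score-discrimination (AUC > 0.60) across 20 seeds at
the study's training size n = 300. Chi-square results are checked
against a from-scratch Pearson oracle, AUCs additionally against an
independent ROC implementation (pROC) where available.

## Limitations

- Synthetic cohorts validate software and statistics, not clinical
  performance; the published cohort-specific AUCs and accuracies cannot
  be reproduced without the patient-level data.
- The grading-point values are taken as fixed inputs; the package does
  not re-derive them (the original fine-tuning was a manual team
  process).
- `split_cohort()` makes no claim to reproduce the original random
  split, whose mechanism was never stated; it is seeded sampling without
  replacement with sizes under the caller's control.
- No imputation: a missing predictor is an explicit error at scoring and
  modelling time.
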
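---
title: "Modeling early post-stroke cognitive recovery from two baseline assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early post-stroke cognitive recovery from two baseline assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecog)
```

## The problem and the model

In the weeks after a stroke, global cognition — measured here with the
Mini-Mental State Examination (MMSE), an integer score from 0 (worst)
to 30 — typically improves quickly at first and then levels off.
`strokecog` models this early phase with two candidate laws on the
days-since-onset axis $t$:

* logarithmic: $f(t) = a + b\,\ln t$ — fast early gain that plateaus;
* linear: $f(t) = a + b\,t$ — constant gain per day.

Here $a$ is the curve's intercept on the transformed axis (for the
logarithmic law, the score at day 1; $\ln 0$ is undefined, so a
same-day-as-onset assessment is encoded as day 1) and $b$ is the slope
of early-phase recovery, in points per ln-day or points per day.

The clinically useful step is *individualization*: two early
assessments $(t_A, s_A)$ and $(t_B, s_B)$ of one patient determine both
parameters exactly. The score change between them,
$\Delta \mathrm{MMSE} = s_B - s_A$, scales the slope:

$$
b_{\log} = \frac{\Delta \mathrm{MMSE}}{\ln t_B - \ln t_A},
\qquad
b_{\mathrm{lin}} = \frac{\Delta \mathrm{MMSE}}{t_B - t_A},
$$

and $a$ is solved so the curve passes through the first anchor. That
is all of `fit_two_point()`; later scores are then forecast with
`predict()`. Because $\ln$ is concave, when $\Delta > 0$ the linear
chord-extrapolation lies strictly above the logarithmic curve at every
day beyond the second anchor — the mechanism by which linear modeling
overestimates recovery. A negative $\Delta$ (a declining patient) is
deliberately not rejected; any anchor pair with distinct days is
valid, the first two assessments being only the default.

Predictions are kept as real numbers for metric computation (means and
SDs of signed differences would otherwise be distorted); `clamp = TRUE`
truncates them into the instrument range $[0, 30]$, and an optional
`round_score` flag rounds for display. No multi-point least-squares
individual fit is offered: the method's point is that two assessments
suffice.

## The two-round workflow

`group_recovery_report()` covers the group-level ("first round")
question — does the cohort's time course look logarithmic? It runs the
Friedman rank test across assessment occasions (patients as blocks),
post-hoc pairwise Wilcoxon signed-rank tests, and OLS fits of score on
$\ln t$ and on $t$ with their $R^2$.

Two statistical surfaces deserve a note:

* **Friedman** is delegated to `stats::friedman.test` (average ranks,
  standard tie correction). A grid in which every patient is constant
  across occasions carries no rank information; the tie-correction
  denominator vanishes there, and we define the result as statistic 0,
  p-value 1 rather than `NaN`.
* **Wilcoxon signed-rank** is implemented in-package: the reported
  statistic is $\min(W^+, W^-)$, zero differences are dropped, tied
  absolute differences receive average ranks, and the p-value is
  *exact* for up to 25 non-zero pairs — including with ties, since the
  sign-flip distribution conditional on the observed ranks remains
  exact. It is computed by subset-sum dynamic programming over doubled
  ranks (doubling keeps half-ranks integral). Beyond 25 pairs a normal
  approximation with tie and continuity correction is used.
  `stats::wilcox.test` was unsuitable as the implementation because it
  abandons exactness whenever ties or zeros occur; it serves instead
  as an independent cross-check in the test suite, alongside a
  brute-force enumeration oracle.
* Post-hoc p-values are reported unadjusted by default (a Bonferroni
  option exists), and all tests are two-sided.

For the group curve fit, `mode = "occasion_summary"` (regress the
per-occasion mean score on the per-occasion mean day) is the default;
`mode = "pooled"` (every observation) is provided for sensitivity.
Group $R^2$ values near 0.95 are plausible only for aggregated
occasion summaries — pooled fits over dozens of noisy patients sit far
lower — so the summary mode is the headline choice.

`run_validation()` covers the individual-level ("second round")
question: for each patient with four assessments, tailor both model
kinds to assessments 1–2, forecast the days of assessments 3 and 4
(clamped, unrounded), and score the forecasts. The anchors never enter
the metrics — a regression test guards exactly this. Per occasion and
model kind the report gives:

* $R^2$ of the OLS regression of actual on predicted scores (the
  "conventional regression" reading of agreement, not a forced
  identity line, so a perfect negative association also scores 1 —
  an accepted property of this measure);
* the mean ± SD of the signed difference actual − predicted, so a
  *negative* mean indicates overprediction;
* the count and percentage of patients whose absolute difference is
  at most 3 points ("correct"). The 3-point tolerance reflects that
  MMSE test-retest differences lie within about 2.4 points, so
  disagreement below 3 integer points is indistinguishable from
  measurement noise. The boundary is inclusive: a difference of
  exactly 3.0 is correct.

The correctness counts of the two models are compared per occasion
with a Pearson $\chi^2$ on the 2×2 table without continuity
correction. This treats the two columns as independent samples even
though both models are scored on the same patients; that is the
classical presentation for this design, and it is kept as the default
for fidelity, while `mcnemar_model_comparison()` offers the paired
test a statistician would prefer. Patients whose prediction is clamped
at 30 stay in all metrics: the ceiling is a real property of the
instrument.

## What the synthetic cohort generator emulates

No patient-level data are available, so `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes. Per
patient:

| quantity | default | rationale |
|---|---|---|
| baseline assessment day | gamma, mean 9.3 d, SD 8.1 d, rounded, ≥ 1 | positive and right-skewed; matches the reported timing moments, which are given only as mean ± SD |
| follow-up offsets | +7, +14, +21 d | weekly reassessment schedule |
| true law | logarithmic | the recovery shape under study; linear available |
| intercept $a$ | normal(19, 4) points | places the baseline median near 23 at the typical baseline day ($19 + 1.8\ln 9.3 \approx 23$) |
| slope magnitude | lognormal, median 1.8 points/ln-day, sdlog 0.5 | positive-mode, sign-free spread; sdlog 0.5 gives a realistic interquartile slope range of roughly 1.3–2.5 and is a package choice, as no individual-level parameters are published |
| decline fraction | 0.1 | a minority of patients deteriorate rather than recover |
| measurement noise | normal, SD 0.87 points | see below |
| observed score | round(clamp(model + noise, 0, 30)) | the MMSE is a bounded integer instrument; clamp first, then round |

The noise SD of 0.87 is calibrated from test-retest reliability: the
difference of two independent measurements then has SD
$0.87\sqrt{2} \approx 1.23$, so about 95% of test-retest differences
fall within ±2.4 points ($1.96 \times 1.23 = 2.41$). On the *rounded*
measurement scale the differences are integers and "within 2.4" means
"within 2", which the discretization concentrates slightly above 95%
(empirically ≈ 95.2%); on the unrounded scale the coverage is ≈ 94.9%.
The property test checks the rounded process, i.e. the measurements
the simulator actually emits.

What the generator does **not** emulate: covariates (lesion site,
white-matter burden, age), dropout or missing assessments (complete
cases only), floor/ceiling-induced skew in the *true* trajectories
(bounds act only on observations), and any correlation between
baseline severity and recovery slope. Passing tests therefore show
that the pipeline is correct and that the logarithmic-versus-linear
ordering follows from the assumed data-generating structure — not that
real cohorts satisfy those assumptions.

Determinism: a seeded configuration reproduces the identical cohort on
every call and restores the caller's RNG state afterwards.

## Sample size for a correlation design

`sample_size_correlation()` reproduces the standard look-up matrix for
detecting a correlation $r$ via the Fisher transform
$C = \tfrac12 \ln\frac{1+r}{1-r}$:

$$ n = \operatorname{round}\!\Big(\big(\tfrac{z_{\alpha/2} + z_\beta}{C}\big)^2\Big) + 3. $$

The squared quotient is rounded to the *nearest* integer before adding
3; this is the convention that reproduces the published table entries
(52 at $r = 0.50$, $\alpha = 0.01$, power 0.90; 40 at $r = 0.60$,
$\alpha = 0.01$, power 0.95) — a ceiling would give 53 and 41.
Quantiles come from `qnorm`, not from a printed table.

```{r power}
sample_size_correlation(r = 0.50, alpha = 0.01, power = 0.90)
```

## Numerical choices and degenerate inputs

* Days are integers ≥ 1 throughout; day 0 inputs are domain errors.
* Identical anchor days are a degenerate-anchor error; $\Delta = 0$
  is *not* an error (flat model).
* The exact Wilcoxon distribution is enumerated over doubled ranks so
  average ranks stay integral; 25 non-zero pairs is the exact/normal
  crossover (at most $2^{25}$ assignments, still exact in double
  arithmetic).
* Actual-on-predicted $R^2$ needs ≥ 3 pairs and a non-constant
  predictor; inside `run_validation()` an undefined $R^2$ is reported
  as `NA` rather than aborting the report.
* A $\chi^2$ table with a zero expected cell is a degenerate-table
  error; an all-zero difference vector in the Wilcoxon test returns a
  flagged degenerate result with p = 1.
* Patients with fewer than four assessments are skipped with a
  warning and listed in the report; an all-skipped cohort is an error.

## Problem sizes used in the checks

The package's own verification uses: 1,000 random anchor pairs for
exact interpolation (tolerance $10^{-9}$); strict
linear-over-logarithmic ordering on 400 positive-delta anchor pairs
over 40 forecast days each; rank-test equivalence against exhaustive
enumeration on over a hundred random instances of up to 8 patients;
200 replicate cohorts of 43 patients for the logarithmic-versus-linear
validation ordering (medians of occasion-4 $R^2$ and %-within-3); and
a 10,000-patient cohort for the timing-distribution calibration.
These sizes make the Monte-Carlo error comfortably smaller than the
margins being tested while keeping the full suite in the low minutes.

## Known limitations

The two-point tailoring is exactly as flexible — and as fragile — as
its anchors: measurement error at either anchor propagates into the
slope inversely with $\ln(t_B/t_A)$, so closely spaced anchors give
unstable forecasts. Forecasts beyond the fourth assessment are out of
scope; nothing here addresses long-term recovery. The unpaired
$\chi^2$ default understates the information in paired correctness
data (use the McNemar variant for inference). And the simulator's
parameter distributions are calibrated stand-ins: acceptance of the
pipeline on synthetic cohorts does not certify the logarithmic law on
any real population.
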
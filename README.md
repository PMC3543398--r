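# strokecog

Modeling and predicting early post-stroke cognitive recovery from
serial Mini-Mental State Examination (MMSE) scores.

## What this is for

Cognitive impairment is common in the acute stage of stroke, and for
patients, families and rehabilitation planners the pressing question
is how far and how fast cognition will recover. In the early weeks,
MMSE scores (integer, 0–30) typically rise steeply and then plateau.
`strokecog` is for clinicians and biostatisticians who want to turn
just **two early assessments** of a patient into a quantitative
forecast of that patient's later scores, and to evaluate how well such
forecasts work.

Two candidate recovery laws on the days-since-onset axis `t` are
supported:

- logarithmic: `f(t) = a + b·ln(t)`
- linear: `f(t) = a + b·t`

Given two assessments `(t_A, s_A)` and `(t_B, s_B)`, the score change
`ΔMMSE = s_B − s_A` fixes the slope — `b = ΔMMSE/(ln t_B − ln t_A)`
for the logarithmic law, `b = ΔMMSE/(t_B − t_A)` for the linear law —
and the intercept is solved so the curve passes exactly through the
anchors. Because `ln` is concave, the linear extrapolation always runs
above the logarithmic one beyond the anchors, so the comparison of the
two laws is a test of whether recovery plateaus.

The package provides:

- `fit_two_point()` / `predict()` — exact two-point tailoring and
  bounded forecasting;
- `group_recovery_report()` — group-level time-course analysis:
  Friedman test across assessment occasions, post-hoc Wilcoxon
  signed-rank tests (exact up to 25 pairs, ties included), and group
  curve fits with R²;
- `run_validation()` — the predicted-versus-actual pipeline: tailor on
  assessments 1–2, forecast assessments 3–4, report R² of actual on
  predicted, signed differences, the %-within-3-points correctness
  rule, and a χ² comparison of the two laws;
- `generate_cohort()` — a calibrated synthetic-cohort simulator
  (gamma-distributed baseline timing, bounded integer scores,
  test-retest noise) so the whole pipeline runs without patient data;
- `sample_size_correlation()` — Fisher-z sample sizes for correlation
  designs;
- a command-line interface (`exec/strokecog`, or `strokecog_cli()`)
  with subcommands `simulate | group | validate | power`.

## Worked example

```r
library(strokecog)

# A patient scored 20 on day 5 and 24 on day 12 post-onset:
m <- fit_two_point(day = c(5, 12), score = c(20, 24), kind = "logarithmic")
m
#> <recovery_model> logarithmic: a + b*ln(t)
#>   a = 12.6465 points, b = 4.56898 points per ln(day)

round(predict(m, c(19, 26), clamp = TRUE), 1)
#> [1] 26.1 27.5
```

The tailored curve forecasts 26.1 points a week later and 27.5 two
weeks later — the plateau shape: 4 points gained over the first week
between anchors, but only ~1.4 more over the following fortnight.

Validating the method on a simulated 43-patient cohort (logarithmic
truth, realistic noise):

```r
coh <- generate_cohort(cohort_config(n_patients = 43, seed = 11))
run_validation(coh, threshold = 3)
#> Two-point prognosis validation: 43 patients (0 skipped), anchors = assessments 1 & 2
#>
#> Assessment 3 (mean day 22.7):
#>   Actual MMSE score, median (IQR):          25 (20-29)
#>   Predicted, logarithmic model:             25 (19.6913-29.0275)
#>   Predicted, linear model:                  26 (20-30)
#>   logarithmic  R^2 = 0.921 | actual-predicted = +0.1+/-1.6 | within 3 pts: 41/43 (95.3%)
#>   linear       R^2 = 0.875 | actual-predicted = -0.4+/-2.1 | within 3 pts: 38/43 (88.4%)
#>   chi-squared (log vs linear correctness): 1.400, p = 0.2368
#>
#> Assessment 4 (mean day 29.7):
#>   Actual MMSE score, median (IQR):          26 (21-29.5)
#>   Predicted, logarithmic model:             25.6495 (19.696-29.6495)
#>   Predicted, linear model:                  28 (20.5-30)
#>   logarithmic  R^2 = 0.901 | actual-predicted = +0.4+/-1.8 | within 3 pts: 41/43 (95.3%)
#>   linear       R^2 = 0.847 | actual-predicted = -0.3+/-2.4 | within 3 pts: 38/43 (88.4%)
#>   chi-squared (log vs linear correctness): 1.400, p = 0.2368
```

Read it as: the logarithmic forecasts agree more tightly with the
actually obtained scores (higher R², smaller spread of errors, more
patients within the 3-point test-retest tolerance), and the linear
model's median prediction drifts above the actual median by the fourth
assessment — its mean error is negative (overprediction), and the gap
widens with the forecast horizon.

The same pipeline from a shell:

```sh
strokecog simulate --n 43 --seed 11 --out cohort.csv
strokecog validate --cohort cohort.csv --out report.json
strokecog power --r 0.5 --alpha 0.01 --power 0.9
```

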
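# Two-point prognosis validation pipeline and its comparison metrics.

test_that("the hand-checkable two-patient cohort reproduces hand arithmetic", {
  rep <- run_validation(hand_cohort())
  rec <- rep$records

  # patient A, logarithmic: b = 4/ln(12/5), model through (5, 20)
  bL <- 4 / log(12 / 5)
  predA <- 20 + bL * log(c(19, 26) / 5)
  # patient A, linear: b = 4/7 -> 28 at day 19, 32 clamped to 30 at day 26
  a_rec <- rec[rec$patient_id == "A", ]
  expect_equal(a_rec$predicted_logarithmic, predA, tolerance = 1e-12)
  expect_equal(a_rec$predicted_linear, c(28, 30), tolerance = 1e-12)

  # patient B is flat: both models predict 15 at both occasions
  b_rec <- rec[rec$patient_id == "B", ]
  expect_equal(b_rec$predicted_logarithmic, c(15, 15))
  expect_equal(b_rec$predicted_linear, c(15, 15))

  # occasion-3 logarithmic metrics by hand: diffs (26 - pred, 15 - 15)
  m <- rep$metrics
  d3 <- c(26 - predA[1], 0)
  row <- m[m$occasion == 3 & m$kind == "logarithmic", ]
  expect_equal(row$diff_mean, mean(d3), tolerance = 1e-12)
  expect_equal(row$diff_sd, sd(d3), tolerance = 1e-12)
  expect_equal(row$n_correct, sum(abs(d3) <= 3))
  expect_equal(row$pct_within, 100 * sum(abs(d3) <= 3) / 2)
  # with only two patients the actual-on-predicted regression is not
  # defined (n < 3) and is reported as NA
  expect_true(is.na(row$r_squared))
})

test_that("correctness classification uses |actual - predicted| <= threshold", {
  expect_equal(classify_within_threshold(20, 23, 3)$n_correct, 1)   # 3.0 in
  expect_equal(classify_within_threshold(20, 23.2, 3)$n_correct, 0) # 3.2 out
  expect_equal(classify_within_threshold(20, 16.8, 3)$n_correct, 0) # symmetric
  expect_equal(classify_within_threshold(20, 20, 0)$n_correct, 1)
  cls <- classify_within_threshold(c(20, 25, 10), c(24, 25, 12), 3)
  expect_equal(cls$n_correct, 2)
  expect_equal(cls$n_total, 3)
  expect_error(classify_within_threshold(1, 1, -1), "threshold")
})

test_that("the 2x2 chi-squared comparison matches hand Pearson arithmetic", {
  same <- chi_square_model_comparison(c(10, 5), c(10, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # E = 20 in every cell, so the statistic is 4 * (10^2 / 20) = 20
  res <- chi_square_model_comparison(c(30, 10), c(10, 30))
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  expect_equal(res$p.value, pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$statistic,
               hand_chisq_2x2(rbind(c(30, 10), c(10, 30))),
               tolerance = 1e-12)

  # swapping the rows leaves the statistic unchanged
  swapped <- chi_square_model_comparison(c(10, 30), c(30, 10))
  expect_equal(swapped$statistic, res$statistic)

  expect_error(chi_square_model_comparison(c(0, 0), c(5, 3)), "non-zero")
  expect_error(chi_square_model_comparison(c(5, 0), c(3, 0)), "degenerate")
})

test_that("the paired McNemar alternative runs on per-patient indicators", {
  set.seed(61)
  cl <- runif(40) < 0.7
  cn <- runif(40) < 0.5
  res <- mcnemar_model_comparison(cl, cn)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  expect_equal(sum(res$table), 40)
})

test_that("actual-on-predicted R^2 matches closed-form least squares", {
  expect_equal(r_squared_actual_vs_predicted(c(1, 2, 3), c(1, 2, 3)), 1)
  # perfect negative association still gives R^2 = 1
  expect_equal(r_squared_actual_vs_predicted(c(1, 2, 3), c(3, 2, 1)), 1)
  got <- r_squared_actual_vs_predicted(c(20, 22, 25, 27), c(21, 21, 26, 26))
  expect_equal(got, 25 / 29, tolerance = 1e-12)
  expect_equal(got, hand_r_squared(c(21, 21, 26, 26), c(20, 22, 25, 27)),
               tolerance = 1e-12)
  expect_error(r_squared_actual_vs_predicted(1:2, 1:2), "length >= 3")
  expect_error(r_squared_actual_vs_predicted(1:3, c(2, 2, 2)), "constant")
})

test_that("anchor assessments are excluded from the metrics", {
  coh <- generate_cohort(cohort_config(n_patients = 43, seed = 11))
  rep <- run_validation(coh)
  expect_true(all(rep$records$occasion %in% c(3, 4)))
  expect_equal(nrow(rep$records), 2 * 43)

  # recompute the occasion-3 logarithmic R^2 with the anchors wrongly
  # included: on noisy data it must differ from the reported value
  series <- cohort_series(coh)
  actual <- c(); pred <- c()
  for (s in series) {
    m <- fit_two_point(s$day[1:2], s$score[1:2], "logarithmic")
    actual <- c(actual, s$score[c(1, 2, 3)])
    pred <- c(pred, pmin(30, pmax(0, predict(m, s$day[c(1, 2, 3)]))))
  }
  wrong <- r_squared_actual_vs_predicted(actual, pred)
  right <- rep$metrics$r_squared[rep$metrics$occasion == 3 &
                                   rep$metrics$kind == "logarithmic"]
  expect_gt(abs(wrong - right), 1e-6)

  expect_error(run_validation(coh, occasions = c(1, 2, 3, 4)),
               "must not include the anchor")
})

test_that("zero-noise logarithmic truth is recovered by the logarithmic model", {
  rep <- run_validation(zero_noise_cohort(n = 43, seed = 101))
  for (occ in c(3, 4)) {
    m <- rep$metrics[rep$metrics$occasion == occ &
                       rep$metrics$kind == "logarithmic", ]
    expect_lte(abs(m$diff_mean), 0.5)
    expect_equal(m$pct_within, 100)
  }
})

test_that("the linear model systematically overestimates under positive logarithmic truth", {
  rep <- run_validation(zero_noise_cohort(n = 43, seed = 102,
                                          decline_fraction = 0))
  m4 <- rep$metrics[rep$metrics$occasion == 4 & rep$metrics$kind == "linear", ]
  # actual - predicted is negative on average when predictions run high
  expect_lt(m4$diff_mean, 0)
  m3 <- rep$metrics[rep$metrics$occasion == 3 & rep$metrics$kind == "linear", ]
  expect_lt(m3$diff_mean, 0)
})

test_that("the within-threshold percentage is monotone in the threshold", {
  coh <- generate_cohort(cohort_config(n_patients = 30, seed = 63))
  pct <- sapply(0:6, function(th) {
    m <- run_validation(coh, threshold = th)$metrics
    m$pct_within[m$occasion == 4 & m$kind == "logarithmic"]
  })
  expect_true(all(diff(pct) >= 0))
})

test_that("short series are skipped with a warning; empty cohorts error", {
  coh <- generate_cohort(cohort_config(n_patients = 5, seed = 64))
  a <- coh$assessments
  # drop patient P0001's fourth assessment
  a <- a[!(a$patient_id == "P0001" & a$day_since_onset ==
             max(a$day_since_onset[a$patient_id == "P0001"])), ]
  expect_warning(rep <- run_validation(mmse_cohort(a)), "skipping 1")
  expect_equal(rep$n_skipped, 1)
  expect_equal(rep$n_used, 4)
  expect_identical(rep$skipped_ids, "P0001")

  short <- mmse_cohort(data.frame(patient_id = "A",
                                  day_since_onset = c(3, 10, 17),
                                  mmse = c(20, 22, 23)))
  expect_warning(expect_error(run_validation(short), "no patient"))
})

test_that("validation report JSON carries every schema-required field", {
  rep <- run_validation(generate_cohort(cohort_config(n_patients = 10,
                                                      seed = 65)))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_validation_report(rep, path)
  got <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(system.file("schemas",
                                           "validation_report.schema.json",
                                           package = "strokecog"),
                               simplifyVector = FALSE)
  expect_true(all(unlist(schema$required) %in% names(got)))
  expect_true(all(unlist(schema$properties$metrics$items$required) %in%
                    names(got$metrics[[1]])))
})
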
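# Second-round validation: tailor per-patient models from the first two
# assessments, forecast the third and fourth, and compare logarithmic
# against linear modeling on predicted-vs-actual agreement.

#' Coefficient of determination of actual on predicted scores
#'
#' R^2 of the ordinary least-squares regression of the actually
#' obtained scores on the model-predicted scores — the conventional
#' agreement measure between forecast and outcome.
#'
#' @param actual,predicted Numeric vectors of equal length >= 3.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared_actual_vs_predicted <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 3L)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  if (stats::var(predicted) == 0)
    stop("cannot fit: predicted values are constant", call. = FALSE)
  summary(stats::lm(actual ~ predicted))$r.squared
}

#' Classify predictions as correct within a tolerance
#'
#' A prediction is correct when the absolute difference between the
#' actual and the (unrounded) predicted score is at most `threshold`
#' points. The default of 3 points reflects that MMSE test-retest
#' differences lie within about 2.4 points, so disagreement within 3
#' points is indistinguishable from measurement noise.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @param threshold Non-negative tolerance in points (default 3).
#' @return List with `n_correct`, `n_total`, and the logical vector
#'   `correct`.
#' @export
classify_within_threshold <- function(actual, predicted, threshold = 3) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single number >= 0", call. = FALSE)
  correct <- abs(actual - predicted) <= threshold
  list(n_correct = sum(correct), n_total = length(correct), correct = correct)
}

#' Chi-squared comparison of two models' correctness counts
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the
#' 2x2 table of correct/incorrect counts under the logarithmic versus
#' the linear model. Note the table treats the two models' counts as
#' independent samples even though they come from the same patients;
#' [mcnemar_model_comparison()] offers the paired alternative.
#'
#' @param counts_log,counts_linear Length-2 vectors
#'   `(n_correct, n_incorrect)` for the two models.
#' @return List with `statistic`, `df`, `p.value`, `table`.
#' @export
chi_square_model_comparison <- function(counts_log, counts_linear) {
  if (length(counts_log) != 2L || length(counts_linear) != 2L ||
      any(c(counts_log, counts_linear) < 0))
    stop("counts must be two (correct, incorrect) pairs of non-negative counts",
         call. = FALSE)
  tab <- rbind(logarithmic = counts_log, linear = counts_linear)
  colnames(tab) <- c("correct", "incorrect")
  if (any(rowSums(tab) == 0))
    stop("each model must have a non-zero total count", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("degenerate table: an expected cell count is zero", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab)
}

#' Paired (McNemar) comparison of two models' correctness
#'
#' McNemar test on the paired per-patient correctness indicators —
#' the statistically preferable alternative to
#' [chi_square_model_comparison()] when both models are evaluated on
#' the same patients.
#'
#' @param correct_log,correct_linear Logical vectors, per-patient
#'   correctness under each model, equal length.
#' @return List with `statistic`, `df`, `p.value`, `table`.
#' @export
mcnemar_model_comparison <- function(correct_log, correct_linear) {
  if (length(correct_log) != length(correct_linear))
    stop("paired indicator vectors must have equal length", call. = FALSE)
  tab <- table(factor(correct_log, levels = c(TRUE, FALSE)),
               factor(correct_linear, levels = c(TRUE, FALSE)),
               dnn = c("logarithmic", "linear"))
  mt <- stats::mcnemar.test(tab)
  list(statistic = unname(mt$statistic), df = unname(mt$parameter),
       p.value = mt$p.value, table = tab)
}

#' Predicted-versus-actual validation of the two-point prognosis
#'
#' For every patient with at least `max(occasions)` assessments:
#' tailor both a logarithmic and a linear model to the two anchor
#' assessments ([fit_two_point()], by default the first two), forecast
#' the scores at the days of the later occasions (by default the 3rd
#' and 4th assessments), and score the forecasts. The anchor
#' assessments never enter the metrics. Predictions are clamped into
#' the instrument range `[0, 30]` (patients at the ceiling stay in all
#' metrics); they are not rounded.
#'
#' Per occasion and model kind the report carries: R^2 of actual on
#' predicted, the mean and SD of the signed difference
#' `actual - predicted`, and the count and percentage of patients
#' within `threshold` points ("correct"). Per occasion, the
#' logarithmic and linear correctness counts are compared with the
#' Pearson chi-squared test.
#'
#' @param cohort An [mmse_cohort()] or long assessments data frame.
#' @param threshold Correctness tolerance in points (default 3).
#' @param anchors Indices (in day order) of the two tailoring
#'   assessments (default `c(1, 2)`).
#' @param occasions Indices of the forecast assessments (default
#'   `c(3, 4)`).
#' @param verbose If `TRUE`, log skipped patients and clamped
#'   predictions via [message()].
#' @return An object of class `validation_report`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 43, seed = 11))
#' run_validation(coh)
#' @export
run_validation <- function(cohort, threshold = 3, anchors = c(1L, 2L),
                           occasions = c(3L, 4L), verbose = FALSE) {
  if (length(anchors) != 2L || anchors[1L] >= anchors[2L])
    stop("'anchors' must be two increasing assessment indices", call. = FALSE)
  if (length(occasions) < 1L)
    stop("at least one forecast occasion is required", call. = FALSE)
  if (any(occasions %in% anchors))
    stop("forecast occasions must not include the anchor assessments",
         call. = FALSE)
  series <- cohort_series(cohort)
  need <- max(c(anchors, occasions))
  enough <- vapply(series, nrow, 0L) >= need
  skipped <- names(series)[!enough]
  if (length(skipped)) {
    warning("skipping ", length(skipped),
            " patient(s) with fewer than ", need, " assessments: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            call. = FALSE)
    if (verbose) for (id in skipped)
      message("skipped patient ", id, ": fewer than ", need, " assessments")
  }
  series <- series[enough]
  if (!length(series))
    stop("no patient has the ", need, " assessments required for validation",
         call. = FALSE)

  recs <- vector("list", length(series))
  n_clamped <- 0L
  for (i in seq_along(series)) {
    s <- series[[i]]
    ad <- s$day[anchors]; as_ <- s$score[anchors]
    m_log <- fit_two_point(ad, as_, "logarithmic")
    m_lin <- fit_two_point(ad, as_, "linear")
    fd <- s$day[occasions]
    raw_log <- predict(m_log, fd)
    raw_lin <- predict(m_lin, fd)
    n_clamped <- n_clamped +
      sum(raw_log < MMSE_MIN | raw_log > MMSE_MAX) +
      sum(raw_lin < MMSE_MIN | raw_lin > MMSE_MAX)
    recs[[i]] <- data.frame(
      patient_id = names(series)[i],
      occasion = occasions,
      day = fd,
      actual = s$score[occasions],
      predicted_logarithmic = pmin(MMSE_MAX, pmax(MMSE_MIN, raw_log)),
      predicted_linear = pmin(MMSE_MAX, pmax(MMSE_MIN, raw_lin)))
  }
  records <- do.call(rbind, recs)
  if (verbose && n_clamped > 0L)
    message(n_clamped, " prediction(s) clamped into [0, 30]")

  kinds <- c("logarithmic", "linear")
  metrics <- do.call(rbind, lapply(occasions, function(occ) {
    sub <- records[records$occasion == occ, , drop = FALSE]
    do.call(rbind, lapply(kinds, function(kind) {
      pred <- sub[[paste0("predicted_", kind)]]
      diffs <- sub$actual - pred
      cls <- classify_within_threshold(sub$actual, pred, threshold)
      r2 <- tryCatch(r_squared_actual_vs_predicted(sub$actual, pred),
                     error = function(e) NA_real_)
      data.frame(occasion = occ, kind = kind, n = nrow(sub),
                 r_squared = r2,
                 diff_mean = mean(diffs), diff_sd = stats::sd(diffs),
                 n_correct = cls$n_correct, n_total = cls$n_total,
                 pct_within = 100 * cls$n_correct / cls$n_total)
    }))
  }))
  comparison <- do.call(rbind, lapply(occasions, function(occ) {
    row <- function(kind) {
      m <- metrics[metrics$occasion == occ & metrics$kind == kind, ]
      c(m$n_correct, m$n_total - m$n_correct)
    }
    cs <- tryCatch(chi_square_model_comparison(row("logarithmic"),
                                               row("linear")),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    data.frame(occasion = occ, chi2_stat = cs$statistic, chi2_p = cs$p.value)
  }))
  structure(list(records = records, metrics = metrics,
                 comparison = comparison, threshold = threshold,
                 anchors = anchors, occasions = occasions,
                 n_used = length(series), n_skipped = length(skipped),
                 skipped_ids = skipped, n_clamped = n_clamped),
            class = "validation_report")
}

med_iqr <- function(x) sprintf("%g (%g-%g)", stats::median(x),
                               stats::quantile(x, 0.25),
                               stats::quantile(x, 0.75))

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Two-point prognosis validation: %d patients (%d skipped), anchors = assessments %s\n",
              x$n_used, x$n_skipped, paste(x$anchors, collapse = " & ")))
  for (occ in x$occasions) {
    sub <- x$records[x$records$occasion == occ, ]
    cat(sprintf("\nAssessment %d (mean day %.1f):\n", occ, mean(sub$day)))
    cat(sprintf("  Actual MMSE score, median (IQR):          %s\n",
                med_iqr(sub$actual)))
    cat(sprintf("  Predicted, logarithmic model:             %s\n",
                med_iqr(sub$predicted_logarithmic)))
    cat(sprintf("  Predicted, linear model:                  %s\n",
                med_iqr(sub$predicted_linear)))
    for (kind in c("logarithmic", "linear")) {
      m <- x$metrics[x$metrics$occasion == occ & x$metrics$kind == kind, ]
      cat(sprintf("  %-12s R^2 = %5.3f | actual-predicted = %+.1f+/-%.1f | within %g pts: %d/%d (%.1f%%)\n",
                  kind, m$r_squared, m$diff_mean, m$diff_sd, x$threshold,
                  m$n_correct, m$n_total, m$pct_within))
    }
    cmp <- x$comparison[x$comparison$occasion == occ, ]
    cat(sprintf("  chi-squared (log vs linear correctness): %.3f, p = %.4g\n",
                cmp$chi2_stat, cmp$chi2_p))
  }
  invisible(x)
}

validation_report_as_list <- function(x) {
  list(threshold = x$threshold, anchors = x$anchors,
       occasions = x$occasions, n_used = x$n_used,
       n_skipped = x$n_skipped, skipped_ids = x$skipped_ids,
       metrics = x$metrics, comparison = x$comparison,
       records = x$records)
}

#' Write a validation report as JSON
#' @param report A [run_validation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(validation_report_as_list(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
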
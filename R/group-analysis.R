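# First-round group analysis: occasion grid, time-course rank tests and
# group-level curve fits with R^2.

#' Arrange a cohort as a patients-by-occasions grid
#'
#' Requires a rectangular cohort: every patient assessed the same
#' number of times. Occasion `j` is a patient's `j`-th assessment in
#' day order.
#'
#' @param cohort An [mmse_cohort()] or long assessments data frame.
#' @return List with `patients`, `occasions`, `scores` (matrix),
#'   `days` (matrix).
#' @export
occasion_matrix <- function(cohort) {
  series <- cohort_series(cohort)
  k <- vapply(series, nrow, 0L)
  if (length(unique(k)) != 1L)
    stop("incomplete grid: patients have differing numbers of assessments (",
         paste(range(k), collapse = "-"), ")", call. = FALSE)
  k <- k[1L]
  if (k < 2L) stop("need at least 2 assessment occasions", call. = FALSE)
  scores <- t(vapply(series, function(s) s$score, numeric(k)))
  days <- t(vapply(series, function(s) s$day, numeric(k)))
  list(patients = names(series),
       occasions = paste0("occasion_", seq_len(k)),
       scores = scores, days = days)
}

#' Group-level recovery curve fit
#'
#' Ordinary least-squares fit of MMSE score on transformed time
#' (`ln(day)` or `day`) at the group level. `mode = "occasion_summary"`
#' (default) regresses the per-occasion mean score on the per-occasion
#' mean day — the aggregation used for headline group fits;
#' `mode = "pooled"` regresses every individual observation.
#'
#' @param cohort An [mmse_cohort()] or long assessments data frame
#'   (rectangular for `occasion_summary`).
#' @param kind `"logarithmic"` or `"linear"`.
#' @param mode `"occasion_summary"` or `"pooled"`.
#' @return List with `kind`, `mode`, `a`, `b`, `r_squared`, `n`
#'   (points entering the regression).
#' @export
fit_group_curve <- function(cohort, kind = c("logarithmic", "linear"),
                            mode = c("occasion_summary", "pooled")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (mode == "occasion_summary") {
    m <- occasion_matrix(cohort)
    day <- colMeans(m$days)
    score <- colMeans(m$scores)
  } else {
    df <- if (inherits(cohort, "mmse_cohort")) cohort$assessments else cohort
    day <- df$day_since_onset
    score <- df$mmse
  }
  tt <- time_transform(day, kind)
  if (length(unique(tt)) < 2L)
    stop("cannot fit: zero variance in the time regressor", call. = FALSE)
  fit <- stats::lm(score ~ tt)
  list(kind = kind, mode = mode,
       a = unname(stats::coef(fit)[1L]),
       b = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       n = length(score))
}

#' Group time-course analysis report
#'
#' The first-round analysis in one call: per-occasion score summaries
#' (median, interquartile range, mean day), the Friedman test across
#' occasions, post-hoc pairwise Wilcoxon signed-rank tests, and group
#' curve fits with R^2 for both the logarithmic and the linear model.
#'
#' @param cohort A rectangular [mmse_cohort()] (or long data frame).
#' @param mode Aggregation for the curve fits, see [fit_group_curve()].
#' @param adjust Post-hoc p-value adjustment, see [pairwise_wilcoxon()].
#' @return An object of class `group_recovery_report`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 20, seed = 3,
#'                                      followup_offsets = c(7, 14)))
#' group_recovery_report(coh)
#' @export
group_recovery_report <- function(cohort,
                                  mode = c("occasion_summary", "pooled"),
                                  adjust = c("none", "bonferroni")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  m <- occasion_matrix(cohort)
  k <- ncol(m$scores)
  summ <- data.frame(
    occasion = seq_len(k),
    mean_day = colMeans(m$days),
    median = apply(m$scores, 2L, stats::median),
    q1 = apply(m$scores, 2L, stats::quantile, probs = 0.25),
    q3 = apply(m$scores, 2L, stats::quantile, probs = 0.75))
  fr <- friedman_timecourse(m$scores)
  pw <- pairwise_wilcoxon(m$scores, adjust = adjust)
  fits <- list(logarithmic = fit_group_curve(cohort, "logarithmic", mode),
               linear = fit_group_curve(cohort, "linear", mode))
  structure(list(n_patients = nrow(m$scores), n_occasions = k,
                 occasion_summary = summ, friedman = fr, pairwise = pw,
                 fits = fits, mode = mode, adjust = adjust),
            class = "group_recovery_report")
}

#' @export
print.group_recovery_report <- function(x, ...) {
  cat(sprintf("Group recovery analysis: %d patients x %d occasions\n",
              x$n_patients, x$n_occasions))
  cat("\nMMSE by occasion (median [IQR] at mean day since onset):\n")
  s <- x$occasion_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  occasion %d (day %5.1f): %g [%g-%g]\n",
                s$occasion[i], s$mean_day[i], s$median[i], s$q1[i], s$q3[i]))
  cat(sprintf("\nFriedman test: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p.value))
  cat(sprintf("Post-hoc Wilcoxon signed-rank (%s):\n",
              if (x$adjust == "none") "unadjusted" else x$adjust))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  occasion %d vs %d: W = %g, p = %.4g\n",
                pw$occasion_1[i], pw$occasion_2[i], pw$statistic[i],
                pw$p.adjusted[i]))
  cat(sprintf("\nGroup curve fits (%s):\n", x$mode))
  for (kind in names(x$fits)) {
    f <- x$fits[[kind]]
    cat(sprintf("  %-12s a = %6.3f, b = %6.3f, R^2 = %.3f\n",
                kind, f$a, f$b, f$r_squared))
  }
  invisible(x)
}

group_report_as_list <- function(x) {
  list(n_patients = x$n_patients, n_occasions = x$n_occasions,
       mode = x$mode, adjust = x$adjust,
       occasion_summary = x$occasion_summary,
       friedman = x$friedman[c("statistic", "df", "p.value")],
       pairwise = x$pairwise,
       fits = lapply(x$fits, function(f)
         f[c("kind", "mode", "a", "b", "r_squared", "n")]))
}

#' Write a group report as JSON
#' @param report A [group_recovery_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_report <- function(report, path) {
  jsonlite::write_json(group_report_as_list(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
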
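# Nonparametric rank tests for the repeated-measures time course.
#
# The Friedman test is delegated to stats::friedman.test (average-rank
# ties, standard tie correction), with the fully degenerate grid — every
# patient constant across occasions — defined as (statistic 0, p 1),
# where the tie-correction denominator would otherwise vanish.
#
# The Wilcoxon signed-rank test is implemented here because the contract
# differs from stats::wilcox.test: the statistic is min(W+, W-), and the
# exact p-value is computed for n <= exact_max even in the presence of
# tied |differences| (the sign-flip distribution conditional on the
# observed ranks is still exact; it is obtained by subset-sum dynamic
# programming over doubled ranks, so half-ranks stay integral).

#' Friedman rank test across assessment occasions
#'
#' Tests for a time-course difference in MMSE scores across repeated
#' assessment occasions (patients as blocks). Uses within-patient
#' average ranks with the standard tie correction; the p-value comes
#' from the chi-squared approximation with `occasions - 1` degrees of
#' freedom. A grid in which every patient scores identically on all
#' occasions carries no rank information and returns statistic 0,
#' p-value 1.
#'
#' @param scores Numeric matrix, patients in rows, occasions in
#'   columns; complete (no `NA`).
#' @return List with `statistic`, `df`, `p.value`, `n` (patients),
#'   `k` (occasions).
#' @export
friedman_timecourse <- function(scores) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores) || anyNA(scores))
    stop("scores must be a complete numeric matrix (no missing cells)",
         call. = FALSE)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L)
    stop("need at least 2 patients and 2 occasions", call. = FALSE)
  if (all(apply(scores, 1L, function(r) diff(range(r)) == 0)))
    return(list(statistic = 0, df = k - 1L, p.value = 1, n = n, k = k))
  ft <- stats::friedman.test(scores)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value, n = n, k = k)
}

# Exact null distribution of 2*W+ for given doubled ranks r2 (integer),
# as counts over 0..sum(r2) out of 2^n equally likely sign assignments.
signed_rank_counts <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) f <- f + c(numeric(r), f[seq_len(total + 1L - r)])
  f
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Paired two-sided test on `x - y`. Zero differences are dropped;
#' absolute differences are ranked with average ranks for ties; the
#' reported statistic is `min(W+, W-)`. For `n <= exact_max` non-zero
#' pairs the p-value is exact (sign-flip distribution conditional on
#' the observed ranks, valid with ties); beyond that, a normal
#' approximation with tie correction and continuity correction is
#' used. If every difference is zero the result is degenerate:
#' statistic 0, p-value 1.
#'
#' @param x,y Paired numeric vectors of equal length >= 1.
#' @param exact_max Largest number of non-zero pairs for which the
#'   exact distribution is enumerated (default 25).
#' @return List with `statistic` (min of the signed-rank sums),
#'   `w_plus`, `w_minus`, `n` (non-zero pairs), `p.value`, `exact`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be paired vectors of equal length >= 1", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, w_plus = 0, w_minus = 0, n = 0L,
                p.value = 1, exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_counts(r2)
    tot <- 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(f[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(f[(w2 + 1L):length(f)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- w_plus - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = min(w_plus, w_minus), w_plus = w_plus, w_minus = w_minus,
       n = n, p.value = p, exact = exact, degenerate = FALSE)
}

#' Post-hoc pairwise Wilcoxon tests between occasions
#'
#' Runs [wilcoxon_signed_rank()] on every pair of occasion columns.
#' P-values are reported unadjusted by default; `adjust =
#' "bonferroni"` multiplies by the number of comparisons.
#'
#' @param scores Patients-by-occasions numeric matrix.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Data frame with columns `occasion_1`, `occasion_2`,
#'   `statistic`, `p.value`, `p.adjusted`.
#' @export
pairwise_wilcoxon <- function(scores, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2L) stop("need at least 2 occasions", call. = FALSE)
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(pr) {
    wt <- wilcoxon_signed_rank(scores[, pr[1L]], scores[, pr[2L]])
    c(statistic = wt$statistic, p.value = wt$p.value)
  })
  out <- data.frame(occasion_1 = pairs[1L, ], occasion_2 = pairs[2L, ],
                    statistic = res["statistic", ], p.value = res["p.value", ])
  out$p.adjusted <- stats::p.adjust(out$p.value, method = adjust,
                                    n = ncol(pairs))
  out
}
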
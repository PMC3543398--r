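# Independent oracles: brute-force / closed-form re-derivations used to
# check the package's statistics. These deliberately avoid the code
# paths (and where easy, even the base helpers) used by the
# implementation.

# Average ranks by pairwise counting (no call to rank()).
counting_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }, numeric(1))
}

# Wilcoxon signed-rank by exhaustive enumeration of all 2^n sign
# assignments of the observed |difference| ranks. Returns the
# min(W+, W-) statistic and the two-sided p-value
# min(1, 2 * min(P(W+ <= w), P(W+ >= w))).
brute_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p.value = 1))
  r <- counting_ranks(abs(d))
  w_plus <- sum(r[d > 0])
  stat <- min(w_plus, sum(r) - w_plus)
  w_all <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(w_all <= w_plus)
  p_ge <- mean(w_all >= w_plus)
  list(statistic = stat, p.value = min(1, 2 * min(p_le, p_ge)))
}

# Friedman statistic from the hand formula with average ranks and the
# standard tie correction; p from the chi-squared approximation.
hand_friedman <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  r <- t(apply(scores, 1, counting_ranks))
  col_sums <- colSums(r)
  tie_term <- sum(apply(r, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  stat <- 12 * sum((col_sums - n * (k + 1) / 2)^2) /
    (n * k * (k + 1) - tie_term / (k - 1))
  list(statistic = stat, df = k - 1,
       p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Closed-form OLS R^2 of y on x: Sxy^2 / (Sxx * Syy).
hand_r_squared <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sxx * syy)
}

# Hand Pearson chi-square on a 2x2 table, no continuity correction.
hand_chisq_2x2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
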
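# Sample size for detecting a correlation, via the Fisher z-transform —
# the formula generating the standard look-up matrix for correlation
# designs.

#' Sample size to detect a correlation
#'
#' Number of subjects needed to detect a correlation of magnitude `r`
#' at two-sided significance level `alpha` with the given power,
#' using the Fisher z method:
#' `C = 0.5 * ln((1 + r) / (1 - r))`,
#' `n = round(((z_{alpha/2} + z_{beta}) / C)^2) + 3`.
#' The squared quotient is rounded to the nearest integer before
#' adding 3 — the convention that reproduces the standard published
#' look-up table (a ceiling would give one more subject at some
#' entries).
#'
#' @param r Expected correlation, in `(-1, 1)` excluding 0; the sign
#'   is ignored.
#' @param alpha Two-sided significance level in `(0, 1)`.
#' @param power Desired power in `(0, 1)`.
#' @return An object of class `sample_size_corr`: list with `n`,
#'   `r`, `alpha`, `power`, `z_alpha`, `z_beta`, `fisher_z`.
#' @examples
#' sample_size_correlation(r = 0.50, alpha = 0.01, power = 0.90)  # n = 52
#' sample_size_correlation(r = 0.60, alpha = 0.01, power = 0.95)  # n = 40
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.80) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(r) || abs(r) >= 1)
    stop("'r' must be a single correlation in (-1, 1)", call. = FALSE)
  if (r == 0)
    stop("'r' must be non-zero: no finite sample size detects a null effect",
         call. = FALSE)
  if (!num1(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!num1(power) || power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  z_alpha <- stats::qnorm(1 - alpha / 2)
  z_beta <- stats::qnorm(power)
  C <- 0.5 * log((1 + abs(r)) / (1 - abs(r)))
  n <- round(((z_alpha + z_beta) / C)^2) + 3
  structure(list(n = as.integer(n), r = r, alpha = alpha, power = power,
                 z_alpha = z_alpha, z_beta = z_beta, fisher_z = C),
            class = "sample_size_corr")
}

#' @export
print.sample_size_corr <- function(x, ...) {
  cat(sprintf(paste0(
    "Sample size for detecting a correlation\n",
    "  r = %g, two-sided alpha = %g, power = %g\n",
    "  z_alpha/2 = %.5f, z_beta = %.5f, Fisher z(r) = %.5f\n",
    "  n = %d\n"),
    x$r, x$alpha, x$power, x$z_alpha, x$z_beta, x$fisher_z, x$n))
  invisible(x)
}
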
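# Sample-size calculation for detecting a correlation coefficient.

#' Power to detect a correlation
#'
#' Power of the test of H0: rho = 0 against a true correlation `r` at sample
#' size `n`, under the bias-corrected Fisher-z approximation: the critical
#' correlation `r_c` is the correlation equivalent of the t critical value
#' with n - 2 degrees of freedom, and
#' power = Phi((atanh(r) + r / (2(n - 1)) - atanh(r_c)) * sqrt(n - 3)).
#'
#' @param n Sample size (may be non-integer; must exceed 3).
#' @param r True correlation, 0 < r < 1.
#' @param alpha Significance level.
#' @param alternative `"one_sided"` or `"two_sided"`.
#' @return Power in (0, 1).
#' @export
power_correlation <- function(n, r, alpha = 0.05,
                              alternative = c("one_sided", "two_sided")) {
  alternative <- match.arg(alternative)
  if (any(n <= 3)) stop_bbb("`n` must exceed 3")
  a <- if (alternative == "one_sided") alpha else alpha / 2
  tc <- qt(1 - a, df = n - 2)
  rc <- sqrt(tc^2 / (tc^2 + n - 2))
  pnorm((atanh(r) + r / (2 * (n - 1)) - atanh(rc)) * sqrt(n - 3))
}

#' Required sample size to detect a correlation
#'
#' Solves `power_correlation(n) = power` for continuous `n` and rounds the
#' solution to the nearest integer.  With the planning values used for a
#' one-week CSF/blood monitoring study -- a true CSF:blood correlation of
#' 0.60, 80% power, one-sided 5% level -- the answer is 15 subjects.
#'
#' @param r Target correlation (effect size), 0 < r < 1.
#' @param power Target power, 0 < power < 1.
#' @param alpha Significance level, 0 < alpha < 0.5.
#' @param alternative `"one_sided"` or `"two_sided"`.
#' @return Integer sample size.
#' @examples
#' required_sample_size(r = 0.60, power = 0.80, alpha = 0.05)
#' @export
required_sample_size <- function(r, power = 0.80, alpha = 0.05,
                                 alternative = c("one_sided", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r >= 1)
    stop_bbb("`r` must be a single value in (0, 1)")
  assert_scalar_prob(power, "power")
  if (alpha <= 0 || alpha >= 0.5) stop_bbb("`alpha` must be in (0, 0.5)")
  f <- function(n) power_correlation(n, r, alpha, alternative) - power
  lo <- 4 + 1e-9
  if (f(lo) >= 0) return(4L)
  hi <- 10
  while (f(hi) < 0 && hi < 1e7) hi <- hi * 2
  if (f(hi) < 0) stop_bbb("no attainable sample size with n >= 4")
  sol <- uniroot(f, c(lo, hi), tol = 1e-9)$root
  as.integer(round(sol))
}
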
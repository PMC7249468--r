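# ARMA(p,q) within-patient correlation structure: specification,
# theoretical correlation matrices, and the unconstrained transform of the
# stationarity/invertibility region used by the model optimisers.

#' ARMA specification
#'
#' Orders and coefficients of the autoregressive-moving-average process used
#' as the within-patient residual correlation structure, with the sign
#' convention `x_t = phi_1 x_{t-1} + ... + e_t + theta_1 e_{t-1} + ...`.
#' Stationarity (AR polynomial roots outside the unit circle) and
#' invertibility (same for the MA polynomial) are enforced.
#'
#' @param p,q Non-negative integer orders.
#' @param phi AR coefficients (length `p`).
#' @param theta MA coefficients (length `q`).
#' @return Object of class `arma_spec`.
#' @export
arma_spec <- function(p = length(phi), q = length(theta),
                      phi = numeric(0), theta = numeric(0)) {
  if (p != length(phi) || q != length(theta))
    stop_bbb("orders and coefficient lengths disagree")
  if (p > 0 && any(Mod(polyroot(c(1, -phi))) <= 1 + 1e-10))
    stop_bbb("non-stationary AR coefficients")
  if (q > 0 && any(Mod(polyroot(c(1, theta))) <= 1 + 1e-10))
    stop_bbb("non-invertible MA coefficients")
  structure(list(p = as.integer(p), q = as.integer(q),
                 phi = as.numeric(phi), theta = as.numeric(theta)),
            class = "arma_spec")
}

#' @export
print.arma_spec <- function(x, ...) {
  cat(sprintf("ARMA(%d,%d)", x$p, x$q))
  if (x$p > 0) cat("  phi:", paste(sprintf("%.3f", x$phi), collapse = ", "))
  if (x$q > 0) cat("  theta:", paste(sprintf("%.3f", x$theta), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Theoretical ARMA correlation matrix
#'
#' Entry (i, j) is the ARMA autocorrelation at lag |i - j| on the regular
#' within-subject grid.  For ARMA(1,1) this is
#' `rho(1) = (1 + phi*theta)(phi + theta) / (1 + theta^2 + 2*phi*theta)`,
#' `rho(k) = phi * rho(k-1)` for k >= 2.
#'
#' @param spec An [arma_spec()].
#' @param n Grid length (matrix dimension).
#' @return n x n symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @export
arma_correlation_matrix <- function(spec, n) {
  stopifnot(inherits(spec, "arma_spec"), n >= 1)
  if (n == 1) return(matrix(1, 1, 1))
  if (spec$p == 0 && spec$q == 0) return(diag(n))
  rho <- ARMAacf(ar = spec$phi, ma = spec$theta, lag.max = n - 1)
  toeplitz(as.numeric(rho))
}

# ---- unconstrained parameterisation -------------------------------------
# Partial-autocorrelation transform (Barndorff-Nielsen & Schou / Monahan):
# maps unconstrained reals through tanh to partial autocorrelations in
# (-1, 1) and then, by the Levinson-Durbin recursion, to a stationary AR
# coefficient vector.  MA coefficients use the same map on the negated
# polynomial, which carries invertibility.

pacf_to_ar <- function(g) {
  a <- numeric(0)
  for (k in seq_along(g)) {
    if (k == 1) a <- g[1]
    else a <- c(a - g[k] * rev(a), g[k])
  }
  a
}

arma_from_unconstrained <- function(u, p, q) {
  phi <- if (p > 0) pacf_to_ar(tanh(u[seq_len(p)])) else numeric(0)
  theta <- if (q > 0) -pacf_to_ar(tanh(u[p + seq_len(q)])) else numeric(0)
  arma_spec(p, q, phi, theta)
}

# Inverse for starting values: AR coefficients -> partial autocorrelations.
ar_to_pacf <- function(a) {
  g <- numeric(length(a))
  for (k in rev(seq_along(a))) {
    g[k] <- a[k]
    if (k > 1) {
      denom <- 1 - a[k]^2
      a <- (a[-k] + a[k] * rev(a[-k])) / denom
    }
  }
  g
}

unconstrained_from_arma <- function(spec) {
  c(if (spec$p > 0) atanh(ar_to_pacf(spec$phi)),
    if (spec$q > 0) atanh(ar_to_pacf(-spec$theta)))
}
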
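# Shared internal helpers.

# Round half away from zero (base round() rounds half to even, which would
# turn 5/16 = 31.25% into 31.2% instead of the conventional 31.3%).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bbb <- function(...) stop(..., call. = FALSE)

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_bbb(sprintf("`%s` must be a single probability in [0, 1]", name))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_bbb(sprintf("`%s` must be positive and finite", name))
}

# Central-difference numerical gradient / Hessian, used for observed
# information of variance parameters (Satterthwaite machinery).
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hess <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- rep(0, k); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    for (j in seq_len(k)) {
      if (j >= i) next
      ej <- rep(0, k); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}
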
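# Fixture builders shared across the suite.  Everything is generated in
# code; seeds are fixed per call site.

# minimal long-format measurement table in canonical units
tiny_measurements <- function() {
  tibble::tibble(
    subject_id = rep("P1", 6),
    analyte = c("S100B_CSF", "S100B_CSF", "S100B_BLOOD", "S100B_BLOOD",
                "ALB_CSF", "ALB_BLOOD"),
    time_h = c(0, 12, 0, 12, 0, 0),
    value = c(7.5, 5.1, 0.4, 0.3, 240, 40),
    unit = c("ug/L", "ug/L", "ug/L", "ug/L", "mg/L", "g/L")
  )
}

# correlated panel with ARMA(1,1) errors for model tests
gen_panel <- function(nsub = 8, nt = 20, phi = 0.7, theta = 0.3,
                      beta = c(1, 0.5, -0.3), sd = 0.5, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nsub), function(i) {
    e <- if (phi == 0 && theta == 0) rnorm(nt, 0, sd) else
      as.numeric(arima.sim(list(ar = phi, ma = theta), nt, sd = sd))
    x <- rnorm(nt)
    data.frame(subject_id = sprintf("S%02d", i), time_h = seq_len(nt),
               x = x, y = beta[1] + beta[2] * seq_len(nt) / 10 +
                 beta[3] * x + e)
  }))
  tibble::as_tibble(out)
}

# brute-force subject-centering oracle for the repeated-measures correlation
rmcorr_oracle <- function(d, x = "x", y = "y", subject = "subject_id") {
  xs <- d[[x]] - ave(d[[x]], d[[subject]])
  ys <- d[[y]] - ave(d[[y]], d[[subject]])
  stats::cor(xs, ys)
}

# direct double-loop evaluation of the cross-correlation formula
ccf_oracle <- function(x, y, max_lag = 4) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sx <- sqrt(mean((x - xb)^2)); sy <- sqrt(mean((y - yb)^2))
  vapply(seq(-max_lag, max_lag), function(l) {
    acc <- 0
    for (k in seq_len(n)) {
      kk <- k + l
      if (kk >= 1 && kk <= n) acc <- acc + (x[k] - xb) * (y[kk] - yb)
    }
    acc / (n * sx * sy)
  }, numeric(1))
}

# fabricate a pooled cross-correlation result whose peak and significance
# are controlled, for attribution-rule tests
fake_ccf <- function(peak, sig = TRUE, max_lag = 4, m = 6) {
  lags <- seq(-max_lag, max_lag)
  base <- if (sig) 0.3 - 0.02 * abs(lags - peak)
          else 0.01 - 0.002 * abs(lags - peak)
  per <- do.call(rbind, lapply(seq_len(m), function(i) {
    jitter <- if (sig) 0.01 * sin(i + lags)
              else 0.7 * sin(i * 2.1 + lags * 1.3)
    tibble::tibble(subject_id = paste0("S", i), lag = lags,
                   r = base + jitter, n_pairs = 10L)
  }))
  pool_cross_correlations(per)
}
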
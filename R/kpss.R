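# KPSS level-stationarity test (null: the series is level-stationary).

# Upper-tail critical values for the level-stationary statistic.
KPSS_LEVEL_CRIT <- c("0.1" = 0.347, "0.05" = 0.463, "0.025" = 0.574,
                     "0.01" = 0.739)

#' KPSS test for level stationarity
#'
#' Statistic `n^-2 * sum_t S_t^2 / lambda^2`, where `S_t` are partial sums
#' of the demeaned series and `lambda^2` is the Bartlett-window long-run
#' variance at the given truncation lag (default `floor(4 * (n/100)^0.25)`).
#' The null hypothesis is stationarity; a large statistic rejects it, which
#' is the screen for whether differencing (ARIMA-style integration) would be
#' needed before ARMA modelling.
#'
#' @param series Numeric series (length >= 8, not constant).
#' @param lag_truncation Bartlett truncation lag; `NULL` for the default.
#' @param level Significance level compared (one of 0.1, 0.05, 0.025, 0.01).
#' @return Object of class `kpss_result` with `statistic`,
#'   `lag_truncation`, `level`, `critical_value` and `verdict`
#'   (`"stationary_not_rejected"` or `"rejected"`).
#' @export
kpss_test <- function(series, lag_truncation = NULL, level = 0.05) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 8) stop_bbb("series too short for the KPSS test (need >= 8)")
  if (!as.character(level) %in% names(KPSS_LEVEL_CRIT))
    stop_bbb("`level` must be one of 0.1, 0.05, 0.025, 0.01")
  e <- series - mean(series)
  if (all(e == 0)) stop_bbb("constant series has zero long-run variance")
  S <- cumsum(e)
  L <- lag_truncation %||% floor(4 * (n / 100)^0.25)
  gamma0 <- mean(e^2)
  lrv <- gamma0
  if (L > 0) {
    for (k in seq_len(L)) {
      w <- 1 - k / (L + 1)
      lrv <- lrv + 2 * w * sum(e[seq_len(n - k)] * e[seq_len(n - k) + k]) / n
    }
  }
  stat <- sum(S^2) / (n^2 * lrv)
  crit <- KPSS_LEVEL_CRIT[[as.character(level)]]
  structure(list(statistic = stat, lag_truncation = L, level = level,
                 critical_value = crit,
                 verdict = if (stat > crit) "rejected"
                           else "stationary_not_rejected"),
            class = "kpss_result")
}

#' @export
print.kpss_result <- function(x, ...) {
  cat(sprintf(
    "KPSS level-stationarity test\n  statistic = %.4f (truncation %d), %g%% critical value %.3f -> %s\n",
    x$statistic, x$lag_truncation, 100 * x$level, x$critical_value,
    x$verdict))
  invisible(x)
}
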
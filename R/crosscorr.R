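# Per-patient lagged cross-correlation of binned biomarker series, pooled
# across patients, with peak-lag attribution across the three compartment
# pairs (CSF vs Q_A, Q_A vs blood, CSF vs blood).

#' Cross-correlation of two binned series for one patient
#'
#' Standard cross-correlation estimator on 12-h lag bins:
#' `r(l) = sum_k (x_k - xbar)(y_{k+l} - ybar) / (N * s_x * s_y)` with means
#' and standard deviations over each full series and N the (geometric mean)
#' number of non-missing bins, constant across lags -- so shifting into
#' shorter overlaps is penalised rather than rescaled, as in the usual ccf
#' convention.  Positive lag means `y` follows `x`.
#'
#' @param x,y Numeric vectors on a common consecutive bin grid (`NA` =
#'   missing bin).
#' @param max_lag Maximum lag magnitude examined (default 4 bins = 48 h).
#' @param min_overlap Minimum number of paired non-missing bins for a lag to
#'   be reported (default 5); also required at lag 0 for the patient to be
#'   usable at all.
#' @return Tibble `lag`, `r`, `n_pairs`; unusable lags carry `NA`.
#' @export
cross_correlation_per_patient <- function(x, y, max_lag = 4, min_overlap = 5) {
  if (length(x) != length(y))
    stop_bbb("`x` and `y` must share one bin grid")
  n <- length(x)
  mx <- sum(!is.na(x)); my <- sum(!is.na(y))
  xb <- mean(x, na.rm = TRUE); yb <- mean(y, na.rm = TRUE)
  sx <- sqrt(mean((x - xb)^2, na.rm = TRUE))
  sy <- sqrt(mean((y - yb)^2, na.rm = TRUE))
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    stop_bbb("zero-variance series")
  N <- sqrt(mx * my)
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    k <- seq_len(n); kk <- k + l
    ok <- kk >= 1 & kk <= n
    prod <- (x[k[ok]] - xb) * (y[kk[ok]] - yb)
    if (sum(!is.na(prod)) < min_overlap) return(NA_real_)
    sum(prod, na.rm = TRUE) / (N * sx * sy)
  }, numeric(1))
  if (is.na(r[lags == 0]))
    stop_bbb("fewer than `min_overlap` paired bins at lag 0")
  tibble::tibble(lag = lags, r = r,
                 n_pairs = vapply(lags, function(l) {
                   k <- seq_len(n); kk <- k + l
                   ok <- kk >= 1 & kk <= n
                   sum(!is.na(x[k[ok]]) & !is.na(y[kk[ok]]))
                 }, integer(1)))
}

# Build per-patient aligned bin vectors for a pair of analytes from a
# lag_series and run the per-patient estimator.
ccf_by_patient <- function(lag_series, x_analyte, y_analyte, max_lag = 4,
                           min_overlap = 5) {
  subjects <- unique(lag_series$subject_id)
  out <- lapply(subjects, function(s) {
    d <- lag_series[lag_series$subject_id == s, ]
    dx <- d[d$analyte == x_analyte, ]
    dy <- d[d$analyte == y_analyte, ]
    if (nrow(dx) == 0 || nrow(dy) == 0) return(NULL)
    span <- max(min(dx$lag), min(dy$lag)):min(max(dx$lag), max(dy$lag))
    if (length(span) < min_overlap) return(NULL)
    x <- setNames(rep(NA_real_, length(span)), span)
    y <- x
    x[as.character(dx$lag[dx$lag %in% span])] <- dx$value[dx$lag %in% span]
    y[as.character(dy$lag[dy$lag %in% span])] <- dy$value[dy$lag %in% span]
    tab <- tryCatch(
      cross_correlation_per_patient(unname(x), unname(y), max_lag, min_overlap),
      error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    tab$subject_id <- s
    tab
  })
  dplyr::bind_rows(out)
}

#' Pool per-patient cross-correlations
#'
#' Pooled mean at each lag is the across-patient mean of the per-patient
#' correlations; the confidence interval is the t interval
#' `mean +/- t_{m-1} * sd / sqrt(m)` over the m contributing patients.  The
#' peak lag maximises the pooled mean, with ties broken toward the smallest
#' lag magnitude and then toward the positive (causal) side.
#'
#' @param per_patient Tibble `subject_id`, `lag`, `r` (as produced by the
#'   per-patient estimator, stacked over patients).
#' @param pair Optional character label `c(x, y)` for printing.
#' @param conf_level Confidence level.
#' @return Object of class `crosscorr_result`: per-lag pooled table,
#'   `peak_lag`, `significant_lags`, and the per-patient table.
#' @export
pool_cross_correlations <- function(per_patient, pair = NULL,
                                    conf_level = 0.95) {
  d <- per_patient[!is.na(per_patient$r), ]
  pooled <- dplyr::summarise(
    dplyr::group_by(d, .data$lag),
    mean_r = mean(.data$r), sd_r = sd(.data$r),
    n_patients = dplyr::n(), .groups = "drop")
  pooled <- pooled[pooled$n_patients >= 2, ]
  if (nrow(pooled) == 0)
    stop_bbb("no lag has >= 2 contributing patients")
  crit <- qt(1 - (1 - conf_level) / 2, df = pooled$n_patients - 1)
  half <- crit * pooled$sd_r / sqrt(pooled$n_patients)
  pooled$ci_low <- pooled$mean_r - half
  pooled$ci_high <- pooled$mean_r + half
  peak_candidates <- which(pooled$mean_r == max(pooled$mean_r))
  peak_lags <- pooled$lag[peak_candidates]
  ord <- order(abs(peak_lags), -sign(peak_lags))
  peak_lag <- peak_lags[ord[1]]
  significant <- pooled$lag[pooled$ci_low > 0 | pooled$ci_high < 0]
  structure(list(pair = pair, pooled = pooled, peak_lag = peak_lag,
                 significant_lags = significant, per_patient = per_patient,
                 conf_level = conf_level),
            class = "crosscorr_result")
}

#' Cross-correlate one analyte pair across a cohort
#'
#' Convenience wrapper: per-patient estimation from a [bin_to_lags()] series
#' followed by pooling.
#'
#' @param lag_series A `lag_series`.
#' @param x_analyte,y_analyte Ordered pair (x leads; positive lag means y
#'   follows x).
#' @inheritParams cross_correlation_per_patient
#' @inheritParams pool_cross_correlations
#' @return A `crosscorr_result`.
#' @export
cross_correlate <- function(lag_series, x_analyte, y_analyte, max_lag = 4,
                            min_overlap = 5, conf_level = 0.95) {
  per_patient <- ccf_by_patient(lag_series, x_analyte, y_analyte, max_lag,
                                min_overlap)
  if (nrow(per_patient) == 0)
    stop_bbb("no patient has enough paired bins for ",
             x_analyte, " vs ", y_analyte)
  pool_cross_correlations(per_patient, pair = c(x_analyte, y_analyte),
                          conf_level = conf_level)
}

#' @export
print.crosscorr_result <- function(x, ...) {
  if (!is.null(x$pair))
    cat(sprintf("Cross-correlation: %s leads, %s follows\n", x$pair[1], x$pair[2]))
  cat(sprintf("  peak lag %d (x %g h bins); significant lags: %s\n",
              x$peak_lag, 12,
              if (length(x$significant_lags)) paste(x$significant_lags, collapse = ", ")
              else "none"))
  print(x$pooled[, c("lag", "mean_r", "ci_low", "ci_high", "n_patients")])
  invisible(x)
}

#' Attribute the CSF-to-blood lag to barrier passage or not
#'
#' Compares peak lags of the three compartment pairs.  A CSF:blood delay is
#' attributed to passage across the disrupted barrier when the Q_A:blood
#' series is delayed identically (both peaks significant); when blood lags
#' CSF by *more* than it lags the barrier signal, the delay cannot be
#' explained by barrier passage and the verdict is `not_bbb_mediated`
#' (Q_A:blood peak significance is not required -- a weak contemporaneous
#' barrier association cannot explain a longer CSF:blood delay either way).
#' Everything else -- non-significant CSF:blood peak, or blood lagging the
#' barrier more than CSF -- is `indeterminate`.
#'
#' @param ccf_csf_qa,ccf_qa_blood,ccf_csf_blood `crosscorr_result`s over the
#'   same lag range for the pairs (CSF, Q_A), (Q_A, blood), (CSF, blood).
#' @return Object of class `lag_attribution`: `verdict` one of
#'   `"bbb_mediated"`, `"not_bbb_mediated"`, `"indeterminate"`, plus the
#'   three peak lags and their significance.
#' @export
attribute_lags <- function(ccf_csf_qa, ccf_qa_blood, ccf_csf_blood) {
  peaks <- c(csf_qa = ccf_csf_qa$peak_lag,
             qa_blood = ccf_qa_blood$peak_lag,
             csf_blood = ccf_csf_blood$peak_lag)
  sig <- c(csf_qa = ccf_csf_qa$peak_lag %in% ccf_csf_qa$significant_lags,
           qa_blood = ccf_qa_blood$peak_lag %in% ccf_qa_blood$significant_lags,
           csf_blood = ccf_csf_blood$peak_lag %in% ccf_csf_blood$significant_lags)
  verdict <- if (!sig[["csf_blood"]]) {
    "indeterminate"
  } else if (peaks[["csf_blood"]] == peaks[["qa_blood"]] && sig[["qa_blood"]]) {
    "bbb_mediated"
  } else if (peaks[["csf_blood"]] > peaks[["qa_blood"]]) {
    "not_bbb_mediated"
  } else {
    "indeterminate"
  }
  structure(list(verdict = verdict, peaks = peaks, peak_significant = sig),
            class = "lag_attribution")
}

#' @export
print.lag_attribution <- function(x, ...) {
  cat(sprintf(
    "Lag attribution: %s\n  peaks: CSF:Q_A %d, Q_A:blood %d, CSF:blood %d\n",
    x$verdict, x$peaks[["csf_qa"]], x$peaks[["qa_blood"]],
    x$peaks[["csf_blood"]]))
  invisible(x)
}

#' Plot pooled cross-correlations
#'
#' Dots are the pooled mean cross-correlation per 0.5-day lag, error bars
#' the across-patient confidence interval; the dashed line marks lag 0.
#'
#' @param result A `crosscorr_result`.
#' @return A ggplot object.
#' @export
plot_cross_correlation <- function(result) {
  d <- result$pooled
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$mean_r)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "lag (0.5 days)", y = "mean cross-correlation",
                  title = if (!is.null(result$pair))
                    paste(result$pair, collapse = " → ") else NULL) +
    ggplot2::theme_minimal()
}
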
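# Graphical-model validation summaries: normalized residuals, fitted vs
# observed agreement, per-subject residual autocorrelation, and robust
# flagging of subjects whose trajectories the model fits poorly.

#' Diagnostics for a fitted clearance model
#'
#' Computes normalized (whitened) residuals, the correlation between fitted
#' and observed values, per-subject residual ACF/PACF, and flags outlier
#' subjects whose root-mean-square normalized residual is a robust-distance
#' outlier (|z| above `flag_threshold` on the median/MAD scale) -- the
#' numeric counterpart of eyeballing one patient tracking far from the
#' population fit.
#'
#' @param fit A `bbb_model_fit`.
#' @param acf_lag_max Maximum lag of the per-subject residual ACF.
#' @param flag_threshold Robust z threshold for flagging a subject.
#' @return Object of class `bbb_diagnostics`: `fitted`, `observed`,
#'   `residuals` (raw), `normalized` (whitened, unit variance),
#'   `fitted_observed_cor`, `subject_summary` (per-subject RMS residual and
#'   robust z), `flagged_subjects`, `acf` (list per subject).
#' @export
model_diagnostics <- function(fit, acf_lag_max = 8, flag_threshold = 3.5) {
  des <- fit$des
  fitted_vals <- drop(des$X %*% fit$beta$estimate)
  resid_raw <- des$y - fitted_vals
  pf <- profile_fit(des, fit$arma, fit$psi_star, fit$Z, fit$method)
  resid_norm <- (pf$yw - drop(pf$Xw %*% fit$beta$estimate)) / sqrt(fit$sigma2)

  subj <- des$subject
  rms <- tapply(resid_norm, subj, function(r) sqrt(mean(r^2)))
  med <- median(rms); madv <- mad(rms)
  z <- if (madv > 0) (rms - med) / madv else rms * 0
  subject_summary <- tibble::tibble(subject_id = names(rms),
                                    rms_norm_resid = as.numeric(rms),
                                    robust_z = as.numeric(z))
  flagged <- subject_summary$subject_id[abs(subject_summary$robust_z) >
                                          flag_threshold]
  acfs <- lapply(split(seq_along(resid_raw), subj), function(ix) {
    r <- resid_raw[ix]
    if (length(r) < 3) return(NULL)
    lm_ <- min(acf_lag_max, length(r) - 1)
    list(acf = drop(acf(r, lag.max = lm_, plot = FALSE)$acf),
         pacf = drop(stats::pacf(r, lag.max = lm_, plot = FALSE)$acf),
         n = length(r))
  })
  structure(list(fitted = fitted_vals, observed = des$y,
                 residuals = resid_raw, normalized = resid_norm,
                 fitted_observed_cor = stats::cor(fitted_vals, des$y),
                 subject_summary = subject_summary,
                 flagged_subjects = flagged, acf = acfs),
            class = "bbb_diagnostics")
}

#' @export
print.bbb_diagnostics <- function(x, ...) {
  cat(sprintf("Model diagnostics: fitted-observed correlation %.3f\n",
              x$fitted_observed_cor))
  if (length(x$flagged_subjects) > 0)
    cat("  flagged subjects:", paste(x$flagged_subjects, collapse = ", "), "\n")
  else cat("  no outlier subjects flagged\n")
  invisible(x)
}

#' Diagnostic plots for a fitted clearance model
#'
#' Fitted-versus-observed scatter and normalized residuals against fitted
#' values.
#'
#' @param diag A `bbb_diagnostics`.
#' @return A list of two ggplot objects.
#' @export
plot_diagnostics <- function(diag) {
  d <- tibble::tibble(fitted = diag$fitted, observed = diag$observed,
                      normalized = diag$normalized)
  p1 <- ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(title = "Fitted vs observed") + ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$normalized)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(title = "Normalized residuals") + ggplot2::theme_minimal()
  list(fitted_observed = p1, residuals = p2)
}
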
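# Repeated-measures ("momentary") correlation: the common within-subject
# association of two longitudinal variables, estimated from the
# common-slope analysis-of-covariance decomposition (y adjusted for subject
# means).

#' Repeated-measures correlation
#'
#' Fits `y ~ subject + x` and converts the adjusted sum of squares of the
#' common slope into a within-subject correlation:
#' `rho = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, with error degrees
#' of freedom `n_obs - n_subjects - 1`.  The p-value is the F test of the
#' common slope; the confidence interval uses the Fisher z transform with
#' standard error `1 / sqrt(df - 1)`.
#'
#' @param data Data frame of paired observations.
#' @param x,y Column names of the two variables.
#' @param subject Column name of the subject identifier.
#' @param conf_level Confidence level for the interval.
#' @return Object of class `rmcorr_result` with fields `rho`, `ci_low`,
#'   `ci_high`, `df`, `p`, `n_subjects`, `n_obs`, `slope`.
#' @export
rmcorr <- function(data, x, y, subject = "subject_id", conf_level = 0.95) {
  d <- data[, c(subject, x, y)]
  names(d) <- c("subject", "x", "y")
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$subject)
  d <- d[d$subject %in% names(counts)[counts >= 2], ]
  if (dplyr::n_distinct(d$subject) < 1)
    stop_bbb("need subjects with >= 2 complete pairs")
  within_var <- tapply(d$x, d$subject, function(v) var(v))
  if (all(within_var == 0 | is.na(within_var)))
    stop_bbb("`x` is constant within every subject")
  d$subject <- factor(d$subject)
  n_obs <- nrow(d)
  n_sub <- nlevels(d$subject)
  df <- n_obs - n_sub - 1
  if (df <= 0) stop_bbb("non-positive error degrees of freedom")

  # with a single subject the subject term is the intercept and the
  # decomposition degrades to the ordinary Pearson correlation (df = n - 2)
  fit <- if (n_sub == 1) lm(y ~ x, data = d) else lm(y ~ subject + x, data = d)
  an <- anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  slope <- coef(fit)[["x"]]
  rho <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  fstat <- an["x", "F value"]
  p <- pf(fstat, 1, df, lower.tail = FALSE)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(df - 1)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(rho = rho, ci_low = tanh(z - crit * se),
                 ci_high = tanh(z + crit * se), df = df, p = p,
                 n_subjects = n_sub, n_obs = n_obs, slope = slope,
                 conf_level = conf_level),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures correlation\n  rho = %.3f (%g%% CI %.3f to %.3f), df = %d, p = %.3g\n  %d subjects, %d observations\n",
    x$rho, 100 * x$conf_level, x$ci_low, x$ci_high, x$df, x$p,
    x$n_subjects, x$n_obs))
  invisible(x)
}
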
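# End-to-end orchestration: simulate (or ingest) -> albumin quotient ->
# lag binning + cross-correlation with attribution -> alignment -> log10 ->
# clearance models -> report, with a reproducibility manifest.

#' Configure a pipeline run
#'
#' Either a simulation profile (with `n` and `seed`) or paths to a
#' long-format measurement CSV (and optionally a demographics CSV) must be
#' given.
#'
#' @param profile `"S100B_like"` or `"NSE_like"` to simulate; `NULL` to
#'   read `measurements_csv`.
#' @param measurements_csv,demographics_csv Input paths (ignored when
#'   simulating).
#' @param n,seed Cohort size and seed for simulation.
#' @param grid_spacing_h Alignment grid spacing.
#' @param max_lag,min_overlap Cross-correlation settings (12-h bins).
#' @param arma ARMA orders `c(p, q)` of the within-subject correlation.
#' @param select_arma If `TRUE`, choose the ARMA orders by AIC over
#'   `arma_grid` instead of using `arma` directly.
#' @param arma_grid Candidate orders for AIC selection (two columns p, q).
#' @param exclude_first_h Early-window exclusion applied to the blood
#'   response before model fitting (the extracranial-peak guard, used for
#'   S100B-family analytes); `0` disables it.
#' @param out_dir Output directory (created).
#' @param write_figures Write cross-correlation and diagnostic figures.
#' @return List of class `run_config`.
#' @export
run_config <- function(profile = "S100B_like", measurements_csv = NULL,
                       demographics_csv = NULL, n = 16, seed = 1,
                       grid_spacing_h = 6, max_lag = 4, min_overlap = 5,
                       arma = c(1, 1), select_arma = FALSE, arma_grid = NULL,
                       exclude_first_h = NULL, out_dir = tempfile("bbbrun"),
                       write_figures = FALSE) {
  if (is.null(profile) && is.null(measurements_csv))
    stop_bbb("either `profile` or `measurements_csv` is required")
  if (!is.null(profile))
    profile <- match.arg(profile, c("S100B_like", "NSE_like"))
  structure(list(profile = profile, measurements_csv = measurements_csv,
                 demographics_csv = demographics_csv, n = n, seed = seed,
                 grid_spacing_h = grid_spacing_h, max_lag = max_lag,
                 min_overlap = min_overlap, arma = arma,
                 select_arma = select_arma, arma_grid = arma_grid,
                 exclude_first_h = exclude_first_h, out_dir = out_dir,
                 write_figures = write_figures),
            class = "run_config")
}

# Identify the biomarker family present in a measurement table.
detect_prefix <- function(measurements) {
  pres <- unique(measurements$analyte)
  for (pre in c("S100B", "NSE"))
    if (all(paste0(pre, c("_CSF", "_BLOOD")) %in% pres)) return(pre)
  stop_bbb("measurements must contain a CSF and a blood series of one biomarker")
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest/simulate, derive the albumin quotient, branch into
#' (a) 12-h lag binning of the original-scale data feeding the three
#' cross-correlations and the lag attribution, and (b) grid interpolation,
#' log10 transform, complete-case filtering and early-window exclusion
#' feeding the momentary correlations and the clearance models (marginal
#' GLS and linear mixed; the mixed fit is preferred unless its
#' random-effect covariance lands on the boundary).  All tables, the
#' verdict, the model summaries, a markdown report and a manifest are
#' written under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  warnings_log <- character(0)
  stage_counts <- list()
  note <- function(...) message("[bbbclear] ", ...)

  # -- ingest ---------------------------------------------------------------
  if (!is.null(config$profile)) {
    note("simulating ", config$profile, " cohort (n = ", config$n,
         ", seed = ", config$seed, ")")
    sim <- make_study_like_cohort(config$profile, n = config$n,
                                  seed = config$seed)
    measurements <- sim$measurements
    demographics <- sim$subjects
    latent <- lapply(sim$latent_params, function(s)
      s[c("subject_id", "csf_amp", "disrupted", "qa_excess",
          "admission_offset_h", "multitrauma")])
  } else {
    note("reading ", config$measurements_csv)
    measurements <- read_long_table(config$measurements_csv)
    demographics <- if (!is.null(config$demographics_csv))
      readr::read_csv(config$demographics_csv, show_col_types = FALSE)
    latent <- NULL
  }
  prefix <- detect_prefix(measurements)
  csf <- paste0(prefix, "_CSF"); blood <- paste0(prefix, "_BLOOD")
  stage_counts$measurements <- nrow(measurements)

  # -- albumin quotient -----------------------------------------------------
  measurements <- derive_qa(measurements)
  stage_counts$with_qa <- nrow(measurements)

  # -- cross-correlation branch (original scale) ---------------------------
  lags <- bin_to_lags(measurements)
  ccf_csf_qa <- cross_correlate(lags, csf, "QA", config$max_lag,
                                config$min_overlap)
  ccf_qa_blood <- cross_correlate(lags, "QA", blood, config$max_lag,
                                  config$min_overlap)
  ccf_csf_blood <- cross_correlate(lags, csf, blood, config$max_lag,
                                   config$min_overlap)
  attribution <- attribute_lags(ccf_csf_qa, ccf_qa_blood, ccf_csf_blood)
  note("peak lags: CSF:QA ", attribution$peaks[["csf_qa"]],
       ", QA:blood ", attribution$peaks[["qa_blood"]],
       ", CSF:blood ", attribution$peaks[["csf_blood"]],
       " -> ", attribution$verdict)

  # -- model branch (aligned grid, log10) ----------------------------------
  grid <- interpolate_to_grid(measurements, config$grid_spacing_h)
  grid <- log10_transform(grid, c(csf, blood, "QA"))
  exclude_h <- config$exclude_first_h %||%
    (if (prefix == "S100B") 12 else 0)
  if (exclude_h > 0)
    grid <- exclude_early_window(grid, blood, exclude_h)
  wide <- complete_cases(grid, c(csf, blood, "QA"))
  stage_counts$grid_rows <- attr(wide, "case_counts")[["input"]]
  stage_counts$complete_cases <- nrow(wide)

  mom_csf_blood <- rmcorr(wide, csf, blood)
  mom_qa_blood <- rmcorr(wide, "QA", blood)

  model_data <- tibble::tibble(
    subject_id = wide$subject_id, time_h = wide$time_h,
    y = wide[[blood]], csf = wide[[csf]], qa = wide$QA,
    time_d = wide$time_h / 24 - mean(wide$time_h / 24))
  model_data$time_d2 <- model_data$time_d^2
  form <- y ~ time_d + time_d2 + csf + qa

  kpss_frac <- {
    res <- vapply(split(model_data, model_data$subject_id), function(d) {
      if (nrow(d) < 8) return(NA)
      kpss_test(d$y)$verdict == "rejected"
    }, logical(1))
    mean(res, na.rm = TRUE)
  }

  if (isTRUE(config$select_arma)) {
    sel <- select_arma_by_aic(form, model_data, orders = config$arma_grid,
                              kind = "marginal_gls", time = "time_h",
                              grid_spacing_h = config$grid_spacing_h)
    pq <- c(sel$best$arma$p, sel$best$arma$q)
    aic_table <- sel$table
  } else {
    pq <- config$arma
    aic_table <- NULL
  }
  gls <- fit_marginal_gls(form, model_data, p = pq[1], q = pq[2],
                          grid_spacing_h = config$grid_spacing_h)
  lmm <- tryCatch(
    fit_linear_mixed(form, model_data, random_time = "time_d",
                     p = pq[1], q = pq[2],
                     grid_spacing_h = config$grid_spacing_h),
    error = function(e) { warnings_log <<- c(warnings_log,
      paste("linear mixed model failed:", conditionMessage(e))); NULL })
  use_lmm <- !is.null(lmm) && !lmm$boundary_psi
  if (!is.null(lmm) && lmm$boundary_psi) {
    warnings_log <- c(warnings_log,
      "mixed-model random-effect covariance not positive definite; marginal model used")
    note("mixed-model covariance on boundary -> marginal model retained")
  }
  final <- if (use_lmm) lmm else gls
  satt <- lapply(final$beta$term, function(tm) satterthwaite_df(final, tm))
  final$beta$df_satt <- vapply(satt, `[[`, numeric(1), "df")
  final$beta$p_satt <- vapply(satt, `[[`, numeric(1), "p")
  diag_ <- model_diagnostics(final)

  results <- list(
    config = config, prefix = prefix, measurements = measurements,
    demographics = demographics, latent = latent, lag_series = lags,
    ccf = list(csf_qa = ccf_csf_qa, qa_blood = ccf_qa_blood,
               csf_blood = ccf_csf_blood),
    attribution = attribution, momentary = list(csf_blood = mom_csf_blood,
                                                qa_blood = mom_qa_blood),
    kpss_rejection_fraction = kpss_frac, aic_table = aic_table,
    gls = gls, lmm = lmm, final = final, diagnostics = diag_,
    stage_counts = stage_counts, warnings = warnings_log)

  write_run_outputs(results, out)
  invisible(results)
}

# Serialise every table, the manifest and the report; figures optional.
write_run_outputs <- function(results, out) {
  cfg <- results$config
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::tibble(
    subject_id = results$measurements$subject_id,
    analyte = results$measurements$analyte,
    time_hours = results$measurements$time_h,
    value = results$measurements$value,
    unit = results$measurements$unit), file.path(out, "measurements.csv"))
  if (!is.null(results$demographics))
    readr::write_csv(results$demographics, file.path(out, "demographics.csv"))
  if (!is.null(results$latent))
    jsonlite::write_json(results$latent, file.path(out, "latent_params.json"),
                         auto_unbox = TRUE, digits = NA)
  readr::write_csv(results$lag_series, file.path(out, "lag_series.csv"))
  pooled <- dplyr::bind_rows(lapply(names(results$ccf), function(nm) {
    d <- results$ccf[[nm]]$pooled; d$pair <- nm; d
  }))
  readr::write_csv(pooled, file.path(out, "crosscorr_pooled.csv"))
  jsonlite::write_json(list(
    verdict = results$attribution$verdict,
    peaks = as.list(results$attribution$peaks),
    peak_significant = as.list(results$attribution$peak_significant)),
    file.path(out, "attribution.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(results$final$beta, file.path(out, "model_table.csv"))
  if (!is.null(results$aic_table))
    readr::write_csv(results$aic_table, file.path(out, "aic_table.csv"))
  jsonlite::write_json(list(
    kind = results$final$kind,
    loglik = results$final$loglik, aic = results$final$aic,
    sigma2 = results$final$sigma2,
    arma = list(p = results$final$arma$p, q = results$final$arma$q,
                phi = results$final$arma$phi, theta = results$final$arma$theta),
    boundary_psi = results$final$boundary_psi,
    momentary = list(
      csf_blood = results$momentary$csf_blood[c("rho", "ci_low", "ci_high", "p")],
      qa_blood = results$momentary$qa_blood[c("rho", "ci_low", "ci_high", "p")]),
    kpss_rejection_fraction = results$kpss_rejection_fraction),
    file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(packageVersion("bbbclear")),
    profile = cfg$profile, seed = cfg$seed, n = cfg$n,
    grid_spacing_h = cfg$grid_spacing_h, max_lag = cfg$max_lag,
    min_overlap = cfg$min_overlap, arma = cfg$arma,
    stage_counts = results$stage_counts, warnings = results$warnings)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report(results), file.path(out, "report.md"))

  if (isTRUE(cfg$write_figures)) {
    figdir <- file.path(out, "figures")
    dir.create(figdir, showWarnings = FALSE)
    for (nm in names(results$ccf)) {
      f <- file.path(figdir, paste0("crosscorr_", nm, ".png"))
      tryCatch({
        grDevices::png(f, width = 700, height = 500)
        print(plot_cross_correlation(results$ccf[[nm]]))
        grDevices::dev.off()
      }, error = function(e) try(grDevices::dev.off(), silent = TRUE))
    }
  }
  invisible(out)
}

#' Render a markdown report of a pipeline run
#'
#' @param results The list returned by [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(results) {
  if (is.null(results) || is.null(results$final)) {
    return(c("# Biomarker clearance report", "",
             "No analytes were analysed."))
  }
  pre <- results$prefix
  mom1 <- results$momentary$csf_blood
  mom2 <- results$momentary$qa_blood
  at <- results$attribution
  fin <- results$final
  sig_terms <- fin$beta$term[fin$beta$p_satt <= 0.05 &
                               fin$beta$term != "(Intercept)"]
  pooled_lines <- unlist(lapply(names(results$ccf), function(nm) {
    d <- results$ccf[[nm]]
    sprintf("| %s | %d | %s |", nm, d$peak_lag,
            if (length(d$significant_lags)) paste(d$significant_lags,
                                                  collapse = " ") else "none")
  }))
  c(sprintf("# %s clearance report", pre), "",
    "## Momentary (repeated-measures) correlations", "",
    sprintf("- %s_CSF vs %s_BLOOD: rho = %.3f (CI %.3f to %.3f), p = %.3g",
            pre, pre, mom1$rho, mom1$ci_low, mom1$ci_high, mom1$p),
    sprintf("- Q_A vs %s_BLOOD: rho = %.3f (CI %.3f to %.3f), p = %.3g",
            pre, mom2$rho, mom2$ci_low, mom2$ci_high, mom2$p), "",
    "## Cross-correlations (0.5-day lags)", "",
    "| pair | peak lag | significant lags |",
    "|------|----------|------------------|",
    pooled_lines, "",
    sprintf("Lag attribution verdict: **%s**", at$verdict), "",
    "## Clearance model", "",
    sprintf("Model: %s with ARMA(%d,%d) errors; logLik %.2f, AIC %.2f.",
            if (fin$kind == "marginal_gls") "marginal GLS" else "linear mixed",
            fin$arma$p, fin$arma$q, fin$loglik, fin$aic),
    sprintf("KPSS rejected stationarity for %.0f%% of subject series.",
            100 * results$kpss_rejection_fraction), "",
    "| term | estimate | SE | df (Satt.) | p (Satt.) |",
    "|------|----------|----|------------|-----------|",
    sprintf("| %s | %.4g | %.3g | %.1f | %.3g |", fin$beta$term,
            fin$beta$estimate, fin$beta$se, fin$beta$df_satt,
            fin$beta$p_satt), "",
    sprintf("Terms retained at the 5%% level: %s.",
            if (length(sig_terms)) paste(sig_terms, collapse = ", ")
            else "none"))
}
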
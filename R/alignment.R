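# Data preparation: within-subject alignment by linear interpolation,
# complete-case filtering, log10 transform, early-window exclusion and
# 12-h lag binning.

#' Interpolate multi-rate series onto a common within-subject grid
#'
#' Analytes sampled at different intervals rarely share time points.  Each
#' subject x analyte series is linearly interpolated onto a regular grid;
#' grid times coinciding with an observation return the observed value, and
#' no value is ever extrapolated outside an analyte's observed span.
#' Interpolation operates on original-scale concentrations; any log
#' transform comes afterwards.
#'
#' @param measurements Canonical-unit measurement tibble (include `QA` rows
#'   via [derive_qa()] before calling if the quotient is needed downstream).
#' @param grid_spacing_h Grid spacing in hours (default 6, the finest
#'   sampling interval of the monitoring design).
#' @return Long tibble `subject_id`, `time_h`, `analyte`, `value`,
#'   `provenance` (`"observed"`, `"interpolated"` or `"missing"`), class
#'   `aligned_grid`.  Duplicate (subject, analyte, time) rows with equal
#'   values are collapsed; with differing values they are an error --
#'   aggregate upstream.
#' @export
interpolate_to_grid <- function(measurements, grid_spacing_h = 6) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements) == 0)
    return(structure(tibble::tibble(subject_id = character(),
                                    time_h = double(), analyte = character(),
                                    value = double(), provenance = character()),
                     class = c("aligned_grid", "tbl_df", "tbl", "data.frame"),
                     grid_spacing_h = grid_spacing_h))
  dup <- dplyr::summarise(
    dplyr::group_by(measurements, .data$subject_id, .data$analyte, .data$time_h),
    n_distinct_value = dplyr::n_distinct(.data$value), .groups = "drop")
  if (any(dup$n_distinct_value > 1)) {
    bad <- dup[dup$n_distinct_value > 1, ][1, ]
    stop_bbb(sprintf(
      "duplicate measurements with differing values for %s/%s at t = %g h; aggregate before interpolation",
      bad$subject_id, bad$analyte, bad$time_h))
  }
  meas <- dplyr::distinct(measurements, .data$subject_id, .data$analyte,
                          .data$time_h, .keep_all = TRUE)

  grid_times <- seq(0, max(meas$time_h), by = grid_spacing_h)
  analytes <- unique(meas$analyte)
  out <- dplyr::group_modify(
    dplyr::group_by(meas, .data$subject_id),
    function(df, key) {
      per_analyte <- lapply(analytes, function(a) {
        d <- df[df$analyte == a, ]
        val <- rep(NA_real_, length(grid_times))
        prov <- rep("missing", length(grid_times))
        if (nrow(d) >= 1) {
          inside <- grid_times >= min(d$time_h) & grid_times <= max(d$time_h)
          if (nrow(d) >= 2) {
            val[inside] <- approx(d$time_h, d$value,
                                  xout = grid_times[inside])$y
            prov[inside] <- "interpolated"
          }
          on_obs <- inside & vapply(grid_times, function(g)
            any(abs(d$time_h - g) < 1e-8), logical(1))
          if (any(on_obs)) {
            idx <- vapply(grid_times[on_obs], function(g)
              which.min(abs(d$time_h - g)), integer(1))
            val[on_obs] <- d$value[idx]
            prov[on_obs] <- "observed"
          }
        }
        tibble::tibble(time_h = grid_times, analyte = a, value = val,
                       provenance = prov)
      })
      dplyr::bind_rows(per_analyte)
    })
  out <- dplyr::ungroup(out)
  structure(out, class = c("aligned_grid", class(tibble::as_tibble(out))),
            grid_spacing_h = grid_spacing_h)
}

#' Complete-case filtering of an aligned grid
#'
#' Pivots the aligned grid wide (one row per subject x grid time) and keeps
#' rows where every required analyte is non-missing.  Retained/dropped
#' counts are reported in the `"case_counts"` attribute.
#'
#' @param grid An `aligned_grid`.
#' @param required_analytes Analytes that must all be present in a row.
#' @return Wide tibble `subject_id`, `time_h`, one column per analyte.
#' @export
complete_cases <- function(grid, required_analytes) {
  wide <- tidyr::pivot_wider(
    grid[, c("subject_id", "time_h", "analyte", "value")],
    names_from = "analyte", values_from = "value")
  missing_req <- setdiff(required_analytes, names(wide))
  if (length(missing_req) > 0)
    stop_bbb("required analytes absent from grid: ",
             paste(missing_req, collapse = ", "))
  keep <- stats::complete.cases(wide[, required_analytes, drop = FALSE])
  out <- wide[keep, ]
  if (nrow(out) == 0)
    warning("complete-case filtering removed every row", call. = FALSE)
  attr(out, "case_counts") <- c(input = nrow(wide), retained = nrow(out),
                                dropped = nrow(wide) - nrow(out))
  out
}

#' Log10-transform selected analytes of an aligned grid
#'
#' @param grid An `aligned_grid`.
#' @param analytes Analytes to transform (elementwise log10); provenance
#'   flags are preserved.
#' @return The grid with transformed values; transformed analytes recorded
#'   in the `"log10_analytes"` attribute.
#' @export
log10_transform <- function(grid, analytes) {
  sel <- grid$analyte %in% analytes & !is.na(grid$value)
  bad <- sel & grid$value <= 0
  if (any(bad)) {
    b <- grid[which(bad)[1], ]
    stop_bbb(sprintf("non-positive value for %s/%s at t = %g h cannot be log10-transformed",
                     b$subject_id, b$analyte, b$time_h))
  }
  grid$value[sel] <- log10(grid$value[sel])
  attr(grid, "log10_analytes") <- union(attr(grid, "log10_analytes"), analytes)
  grid
}

#' Exclude an early post-trauma window for one analyte
#'
#' S100B in blood carries an extracranial contribution during roughly the
#' first 12 h after multitrauma; model fitting for such an analyte excludes
#' that window.  The window is half-open: a row at exactly `cutoff_h`
#' survives.  Idempotent.
#'
#' @param grid An `aligned_grid` (long) or wide complete-case table.
#' @param analyte Analyte whose early rows are dropped; for a wide table the
#'   whole row is dropped (the response is undefined there).
#' @param cutoff_h Exclusion cutoff in hours (default 12).
#' @return The filtered table.
#' @export
exclude_early_window <- function(grid, analyte, cutoff_h = 12) {
  if ("analyte" %in% names(grid)) {
    drop <- grid$analyte == analyte & grid$time_h < cutoff_h
    out <- grid[!drop, ]
  } else {
    out <- grid[grid$time_h >= cutoff_h, ]
  }
  out
}

#' Bin measurements into half-day lags
#'
#' Cross-correlation operates on original-scale (untransformed) data
#' subdivided into 0.5-day (12 h) bins; multiple measurements within one bin
#' are averaged.  Bins are half-open `[12k, 12(k+1))`: a measurement at
#' exactly 12 h belongs to bin 1.
#'
#' @param measurements Canonical-unit measurement tibble.
#' @param bin_width_h Bin width in hours (default 12).
#' @return Tibble `subject_id`, `analyte`, `lag` (bin index k), `value`
#'   (bin mean), `n_obs`; class `lag_series`.
#' @export
bin_to_lags <- function(measurements, bin_width_h = 12) {
  if (nrow(measurements) == 0)
    return(structure(tibble::tibble(subject_id = character(),
                                    analyte = character(), lag = integer(),
                                    value = double(), n_obs = integer()),
                     class = c("lag_series", "tbl_df", "tbl", "data.frame"),
                     bin_width_h = bin_width_h))
  out <- dplyr::summarise(
    dplyr::group_by(measurements, .data$subject_id, .data$analyte,
                    lag = as.integer(floor(.data$time_h / bin_width_h))),
    value = mean(.data$value), n_obs = dplyr::n(), .groups = "drop")
  structure(out, class = c("lag_series", class(out)),
            bin_width_h = bin_width_h)
}
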
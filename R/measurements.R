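# Long-format measurement ingestion with unit normalisation.

# Conversion factors into the canonical unit of each analyte.  Unicode and
# ASCII spellings of "ug/L" are accepted; ng/mL is numerically identical to
# ug/L.  Anything not listed for an analyte is an unparsable unit and the row
# is rejected.
unit_factor <- function(analyte, unit) {
  u <- gsub("µ|μ", "u", tolower(trimws(unit)))
  u <- gsub("\\s+", "", u)
  biomarker <- c("ug/l" = 1, "ng/ml" = 1, "mg/l" = 1000)
  tabs <- list(
    S100B_CSF = biomarker, S100B_BLOOD = biomarker,
    NSE_CSF = biomarker, NSE_BLOOD = biomarker,
    ALB_CSF = c("mg/l" = 1, "g/l" = 1000, "ug/l" = 0.001, "mg/dl" = 10),
    ALB_BLOOD = c("g/l" = 1, "mg/l" = 0.001, "g/dl" = 10)
  )
  tab <- tabs[[analyte]]
  if (is.null(tab) || !u %in% names(tab)) return(NA_real_)
  unname(tab[u])
}

#' Read a long-format measurement table
#'
#' Reads delimited text with columns `subject_id`, `analyte`, `time_hours`,
#' `value`, `unit` and returns a tibble of measurements in canonical units
#' (biomarkers in ug/L, CSF albumin in mg/L, blood albumin in g/L).  Rows
#' with an unknown analyte, a non-positive concentration, a negative time or
#' an unparsable unit are rejected; rejected rows are reported via a message
#' and kept, with their reason, in the `"rejected"` attribute of the result.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param delim Field delimiter.
#' @return A tibble with columns `subject_id`, `analyte`, `time_h`, `value`,
#'   `unit` (canonical), ordered by subject, analyte and time.
#' @seealso [write_long_table()]
#' @export
read_long_table <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    subject_id = readr::col_character(),
    analyte = readr::col_character(),
    time_hours = readr::col_double(),
    value = readr::col_double(),
    unit = readr::col_character()
  ), progress = FALSE)
  normalize_measurements(raw)
}

# Workhorse shared by read_long_table() and in-memory tables.
normalize_measurements <- function(raw) {
  required <- c("subject_id", "analyte", "time_hours", "value", "unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop_bbb("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    out <- tibble::tibble(subject_id = character(), analyte = character(),
                          time_h = double(), value = double(),
                          unit = character())
    attr(out, "rejected") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }
  reason <- rep(NA_character_, nrow(raw))
  reason[!(raw$analyte %in% ANALYTES)] <- "unknown analyte"
  fac <- rep(NA_real_, nrow(raw))
  ok <- is.na(reason)
  fac[ok] <- mapply(unit_factor, raw$analyte[ok], raw$unit[ok])
  reason[ok & is.na(fac)] <- "unparsable unit"
  reason[is.na(reason) & (!is.finite(raw$value) | raw$value <= 0)] <-
    "non-positive value"
  reason[is.na(reason) & (!is.finite(raw$time_hours) | raw$time_hours < 0)] <-
    "negative time"
  keep <- is.na(reason)
  out <- tibble::tibble(
    subject_id = raw$subject_id[keep],
    analyte = raw$analyte[keep],
    time_h = raw$time_hours[keep],
    value = raw$value[keep] * fac[keep],
    unit = unname(CANONICAL_UNITS[raw$analyte[keep]])
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$analyte, .data$time_h)
  rejected <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  if (nrow(rejected) > 0)
    message(nrow(rejected), " row(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))
  attr(out, "rejected") <- rejected
  out
}

#' Write a measurement table in the long interchange format
#'
#' Inverse of [read_long_table()] on canonical-unit data: writing and
#' re-reading is the identity.
#'
#' @param measurements Tibble as returned by [read_long_table()].
#' @param path Output path (CSV).
#' @export
write_long_table <- function(measurements, path) {
  out <- tibble::tibble(
    subject_id = measurements$subject_id,
    analyte = measurements$analyte,
    time_hours = measurements$time_h,
    value = measurements$value,
    unit = measurements$unit
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Derive albumin-quotient pseudo-measurements
#'
#' Computes the albumin quotient at every (subject, time) where both CSF and
#' blood albumin were measured, and appends the result as analyte `"QA"`
#' (dimensionless, unit `"1"`).  Downstream alignment and correlation treat
#' the quotient exactly like a measured analyte.
#'
#' @param measurements Canonical-unit measurement tibble.
#' @return The input with `QA` rows appended.
#' @export
derive_qa <- function(measurements) {
  alb <- measurements[measurements$analyte %in% c("ALB_CSF", "ALB_BLOOD"), ]
  if (nrow(alb) == 0) return(measurements)
  wide <- tidyr::pivot_wider(alb[, c("subject_id", "analyte", "time_h", "value")],
                             names_from = "analyte", values_from = "value")
  if (!all(c("ALB_CSF", "ALB_BLOOD") %in% names(wide))) return(measurements)
  wide <- wide[!is.na(wide$ALB_CSF) & !is.na(wide$ALB_BLOOD), ]
  qa <- tibble::tibble(
    subject_id = wide$subject_id,
    analyte = "QA",
    time_h = wide$time_h,
    value = compute_qa(wide$ALB_CSF, wide$ALB_BLOOD),
    unit = "1"
  )
  dplyr::bind_rows(measurements, qa)
}
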
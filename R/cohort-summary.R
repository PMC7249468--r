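# Cohort demographics: access to the bundled severe-TBI cohort table and
# the median/IQR + count/% summariser.

#' Demographics of the 16-patient severe TBI monitoring cohort
#'
#' Individual admission demographics, injury scores, CT classifications and
#' 6-month outcome for the published 16-patient severe traumatic brain
#' injury cohort monitored with continuous ventricular CSF drainage that
#' motivates this package's defaults.  Columns: `patient` (study number;
#' one screened patient was excluded before analysis, so the numbering has a
#' gap), `age` (years), `sex` (M/F), `gcs` (Glasgow Coma Scale 3-15),
#' `pupils` (0 = both reactive, 1 = unilateral unresponsive, 2 = bilateral
#' unresponsive), `multitrauma` (0/1), `ais_head`, `ais_nonhead`
#' (Abbreviated Injury Scale 0-5 at admission), `iss` (Injury Severity
#' Score 1-75), `marshall` (CT classification; V and VI collapse to "mass
#' lesion"), `rotterdam` (1-6), `stockholm` (tally-based score),
#' `progression` (CT lesion progression 0/1), `gos` (Glasgow Outcome Scale
#' 1-5 at 6 months).
#'
#' @return Tibble with 16 rows.
#' @export
tbi_demographics <- function() {
  path <- system.file("extdata", "severe_tbi_demographics.csv",
                      package = "bbbclear", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    patient = readr::col_integer(), age = readr::col_integer(),
    sex = readr::col_character(), gcs = readr::col_integer(),
    pupils = readr::col_integer(), multitrauma = readr::col_integer(),
    ais_head = readr::col_integer(), ais_nonhead = readr::col_integer(),
    iss = readr::col_integer(), marshall = readr::col_character(),
    rotterdam = readr::col_integer(), stockholm = readr::col_double(),
    progression = readr::col_integer(), gos = readr::col_integer()
  ))
}

#' Summarise a cohort demographics table
#'
#' Continuous variables are summarised as median (IQR), categorical
#' variables as count (%).  Percentages are rounded half away from zero to
#' one decimal, so e.g. 5/16 prints as 31.3%.  The quantile rule for the
#' IQR is configurable because published IQRs do not always identify their
#' convention; only the median is convention-free.
#'
#' @param records Data frame of one row per subject.
#' @param continuous,categorical Column names to treat as continuous or
#'   categorical; defaults match [tbi_demographics()].
#' @param quantile_type Passed to [stats::quantile()] (default 7, the R
#'   default).
#' @return Tibble with columns `variable`, `level`, `n`, `pct`, `median`,
#'   `q1`, `q3` and a preformatted `summary` string.
#' @export
summarize_cohort <- function(records,
                             continuous = c("age", "gcs", "ais_head",
                                            "ais_nonhead", "iss", "rotterdam",
                                            "stockholm"),
                             categorical = c("sex", "pupils", "multitrauma",
                                             "marshall", "progression", "gos"),
                             quantile_type = 7) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_bbb("`records` must contain at least one subject")
  continuous <- intersect(continuous, names(records))
  categorical <- intersect(categorical, names(records))
  n_total <- nrow(records)

  cont <- lapply(continuous, function(v) {
    x <- records[[v]]
    qs <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = quantile_type,
                   names = FALSE)
    tibble::tibble(
      variable = v, level = NA_character_, n = sum(!is.na(x)), pct = NA_real_,
      median = qs[2], q1 = qs[1], q3 = qs[3],
      summary = sprintf("%g (%g-%g)", qs[2], qs[1], qs[3])
    )
  })
  cat_ <- lapply(categorical, function(v) {
    x <- records[[v]]
    tab <- table(x, useNA = "no")
    tibble::tibble(
      variable = v, level = names(tab), n = as.integer(tab),
      pct = round_half_away(100 * as.integer(tab) / n_total, 1),
      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      summary = sprintf("%d (%.1f%%)", as.integer(tab),
                        round_half_away(100 * as.integer(tab) / n_total, 1))
    )
  })
  dplyr::bind_rows(c(cont, cat_))
}
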
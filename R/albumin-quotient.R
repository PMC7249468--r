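# Albumin quotient and age-banded reference flagging.

#' CSF:blood albumin quotient
#'
#' The albumin quotient Q_A = albumin_CSF / albumin_blood is the standard
#' measure of blood-brain (and blood-CSF) barrier integrity: albumin has no
#' intracranial synthesis, so an elevated quotient reflects leakage across a
#' disrupted barrier.  CSF albumin is conventionally reported in mg/L and
#' blood albumin in g/L; the quotient is computed after converting CSF
#' albumin to g/L and is dimensionless.
#'
#' @param alb_csf CSF albumin in mg/L (positive).
#' @param alb_blood Blood albumin in g/L (positive).
#' @return Dimensionless quotient, `(alb_csf / 1000) / alb_blood`.
#' @examples
#' compute_qa(240, 40)  # 0.006, the upper reference bound for ages 15-29
#' @export
compute_qa <- function(alb_csf, alb_blood) {
  if (any(!is.finite(alb_csf)) || any(alb_csf <= 0))
    stop_bbb("invalid concentration: `alb_csf` must be positive")
  if (any(!is.finite(alb_blood)) || any(alb_blood <= 0))
    stop_bbb("invalid concentration: `alb_blood` must be positive")
  (alb_csf / 1000) / alb_blood
}

#' Laboratory reference intervals
#'
#' Age-banded reference intervals used for flagging: CSF albumin, blood
#' albumin and the albumin quotient carry age-dependent bounds with gaps
#' between the defined bands (no band is defined for ages 30-49 for CSF
#' albumin and Q_A, nor for 41-70 for blood albumin); the biomarkers carry a
#' single strict upper bound.  Upper bounds are strict ("< x"), so a value
#' exactly at the bound flags as above.
#'
#' @return Tibble with columns `analyte`, `age_min`, `age_max` (inclusive
#'   lower, exclusive upper), `lower`, `upper`.
#' @export
reference_intervals <- function() {
  tibble::tribble(
    ~analyte,      ~age_min, ~age_max, ~lower, ~upper,
    "ALB_CSF",           15,       30,     NA,    260,
    "ALB_CSF",           50,      Inf,     NA,    400,
    "ALB_BLOOD",          0,       41,     36,     48,
    "ALB_BLOOD",         71,      Inf,     34,     45,
    "QA",                15,       30,     NA,  0.006,
    "QA",                50,      Inf,     NA,  0.009,
    "S100B_CSF",          0,      Inf,     NA,      5,
    "S100B_BLOOD",        0,      Inf,     NA,   0.11,
    "NSE_CSF",            0,      Inf,     NA,     13,
    "NSE_BLOOD",          0,      Inf,     NA,     18
  )
}

#' Flag a value against its age-appropriate reference interval
#'
#' @param analyte One of the measured analytes or `"QA"`.
#' @param value Concentration in the analyte's canonical unit (or the
#'   dimensionless quotient for `"QA"`).
#' @param age Age in years; used to pick the reference band.
#' @return One of `"below"`, `"within"`, `"above"`, or `"undefined_band"`
#'   when no reference band covers that age (ages 30-49 for CSF albumin and
#'   Q_A; 41-70 for blood albumin).  Classification is never interpolated
#'   across the gap.
#' @examples
#' flag_against_reference("S100B_BLOOD", 0.12, age = 40)  # "above"
#' flag_against_reference("QA", 0.005, age = 25)          # "within"
#' flag_against_reference("QA", 0.007, age = 40)          # "undefined_band"
#' @export
flag_against_reference <- function(analyte, value, age) {
  n <- max(length(analyte), length(value), length(age))
  analyte <- rep_len(analyte, n); value <- rep_len(value, n)
  age <- rep_len(age, n)
  ref <- reference_intervals()
  vapply(seq_len(n), function(i) {
    if (!analyte[i] %in% ref$analyte)
      stop_bbb("no reference interval defined for analyte ", analyte[i])
    band <- ref[ref$analyte == analyte[i] &
                  ref$age_min <= age[i] & age[i] < ref$age_max, ]
    if (nrow(band) == 0) return("undefined_band")
    if (!is.na(band$lower) && value[i] < band$lower) return("below")
    if (value[i] >= band$upper) return("above")
    "within"
  }, character(1))
}
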
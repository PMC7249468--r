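# Seeded two-compartment synthetic cohort generator.
#
# Latent model per subject (time t in hours since trauma):
#   CSF biomarker      C(t) = A * exp(-lambda_c * t)
#   albumin quotient   Q(t) = qa_base + D * g(t), with g a pure exponential
#                      decay or (when qa_rise_halflife_h > 0) a normalised
#                      rise-then-decay difference of exponentials, and D = 0
#                      for subjects without barrier disruption
#   blood biomarker    dB/dt = k_bbb * Q(t - d_bbb) * C(t - d_bbb)
#                              + k_alt * C(t - d_alt) - lambda_e * B
# integrated by forward Euler, B(0) a small physiologic baseline, delayed
# terms zero while the delayed time is negative.  Blood elimination is fast
# (flip-flop kinetics): the observed terminal decline of the blood series
# reflects the input decay, which is how the effective serum half-lives
# reported for these biomarkers (about 24 h for S100B, 48-72 h for NSE)
# arise here.

#' Configuration of a synthetic monitoring cohort
#'
#' All rates are parameterised as half-lives in hours.  Defaults give an
#' S100B-like biomarker: barrier-dependent transfer only, 12 h transport
#' delay, CSF decay and barrier normalisation chosen so the observed blood
#' decline has an effective half-life near 24 h.
#'
#' @param n_subjects Number of subjects.
#' @param duration_h Follow-up in hours (default one week).
#' @param csf_amp_mu,csf_amp_cv Median and lognormal coefficient of
#'   variation of the CSF release amplitude A (ug/L).
#' @param csf_decay_halflife_h Half-life of the CSF decay.
#' @param qa_disrupted_prob Probability that a subject has a disrupted
#'   barrier (D > 0).
#' @param qa_base Baseline albumin quotient of an intact barrier.
#' @param qa_excess_mu,qa_excess_cv Median and CV of the initial (or peak)
#'   excess quotient D in disrupted subjects.
#' @param qa_decay_halflife_h Half-life of barrier normalisation.
#' @param qa_rise_halflife_h Half-life of the disruption build-up; 0 means
#'   the disruption is maximal at trauma and decays monotonically.
#' @param k_bbb Transfer coefficient of the barrier-dependent route
#'   (per hour per unit Q_A).
#' @param k_alt Transfer coefficient of the barrier-independent route
#'   (per hour).
#' @param delay_bbb_h,delay_alt_h Transport delays of the two routes.
#' @param blood_halflife_h Blood elimination half-life.  Deliberately fast
#'   (default 1 h): under flip-flop kinetics the observed serum decline is
#'   then governed by the input decay, matching the effective serum
#'   half-lives reported for brain biomarkers, while blood tracks its
#'   delayed input with essentially the transport delay alone.
#' @param blood_baseline Physiologic blood baseline B(0) (ug/L).
#' @param extracranial_spike `"off"` or `"on"`: additive S100B-like blood
#'   bump in multitrauma subjects decaying to ~0 by 12 h.
#' @param spike_amp Amplitude of that bump (ug/L).
#' @param multitrauma_prob Probability a subject is a multitrauma case.
#' @param noise_cv Lognormal assay coefficient of variation.
#' @param biomarker_interval_h,albumin_interval_h Sampling intervals.
#' @param admission_offset_range_h Range (hours after trauma) in which
#'   monitoring starts; sampling schedules start at this per-subject offset.
#' @param csf_pool_window_h CSF observations are means over the pool of CSF
#'   collected during this preceding window (continuous-drainage design).
#' @param alb_blood_mu,alb_blood_sd Between-subject mean and SD of blood
#'   albumin (g/L), used to decompose the latent quotient into the two
#'   observed albumin series.
#' @param analyte_prefix `"S100B"` or `"NSE"`: names the emitted CSF/blood
#'   analytes.
#' @param euler_step_h Forward-Euler step (must be <= 1 h).
#' @param seed Optional integer; stored for provenance and used by
#'   [simulate_cohort()] when set.
#' @return Object of class `cohort_config`.
#' @seealso [make_study_like_cohort()] for study-calibrated profiles.
#' @export
cohort_config <- function(n_subjects = 16,
                          duration_h = 168,
                          csf_amp_mu = 30,
                          csf_amp_cv = 0.4,
                          csf_decay_halflife_h = 36,
                          qa_disrupted_prob = 0.5,
                          qa_base = 0.005,
                          qa_excess_mu = 0.02,
                          qa_excess_cv = 0.3,
                          qa_decay_halflife_h = 72,
                          qa_rise_halflife_h = 0,
                          k_bbb = 0.5,
                          k_alt = 0,
                          delay_bbb_h = 12,
                          delay_alt_h = 24,
                          blood_halflife_h = 1,
                          blood_baseline = 0.02,
                          extracranial_spike = c("off", "on"),
                          spike_amp = 0.5,
                          multitrauma_prob = 0.375,
                          noise_cv = 0.15,
                          biomarker_interval_h = 6,
                          albumin_interval_h = 12,
                          admission_offset_range_h = c(2, 6),
                          csf_pool_window_h = 6,
                          alb_blood_mu = 40,
                          alb_blood_sd = 3,
                          analyte_prefix = c("S100B", "NSE"),
                          euler_step_h = 0.1,
                          seed = NULL) {
  extracranial_spike <- match.arg(extracranial_spike)
  analyte_prefix <- match.arg(analyte_prefix)
  cfg <- as.list(environment())
  for (nm in c("duration_h", "csf_amp_mu", "csf_decay_halflife_h",
               "qa_excess_mu", "qa_decay_halflife_h", "blood_halflife_h",
               "biomarker_interval_h", "albumin_interval_h", "euler_step_h"))
    assert_positive(cfg[[nm]], nm)
  if (qa_base < 0) stop_bbb("`qa_base` must be >= 0")
  assert_scalar_prob(qa_disrupted_prob, "qa_disrupted_prob")
  assert_scalar_prob(multitrauma_prob, "multitrauma_prob")
  if (euler_step_h > 1) stop_bbb("`euler_step_h` must be <= 1 hour")
  if (n_subjects < 1) stop_bbb("`n_subjects` must be >= 1")
  if (noise_cv < 0) stop_bbb("`noise_cv` must be >= 0")
  if (k_bbb < 0 || k_alt < 0) stop_bbb("transfer coefficients must be >= 0")
  structure(cfg, class = "cohort_config")
}

# lognormal draw with median m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  rlnorm(n, meanlog = log(m), sdlog = sqrt(log(1 + cv^2)))
}

# multiplicative assay noise with unit mean
noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Draw subject-level latent parameters
#'
#' Uses the current RNG state; callers seed once per cohort.
#'
#' @param config A [cohort_config()].
#' @param subject_id Identifier for the subject.
#' @return List of subject parameters (amplitude, disruption status and
#'   excess quotient, admission offset, multitrauma flag, blood albumin
#'   level).
#' @export
draw_subject_params <- function(config, subject_id) {
  disrupted <- runif(1) < config$qa_disrupted_prob
  list(
    subject_id = subject_id,
    csf_amp = rlnorm_cv(1, config$csf_amp_mu, config$csf_amp_cv),
    disrupted = disrupted,
    qa_excess = if (disrupted)
      rlnorm_cv(1, config$qa_excess_mu, config$qa_excess_cv) else 0,
    admission_offset_h = runif(1, config$admission_offset_range_h[1],
                               config$admission_offset_range_h[2]),
    multitrauma = runif(1) < config$multitrauma_prob,
    alb_blood = max(rnorm(1, config$alb_blood_mu, config$alb_blood_sd), 20)
  )
}

#' Simulate one subject's latent trajectories
#'
#' Deterministic given the subject parameters: all randomness lives in
#' [draw_subject_params()] and [observe_cohort()].
#'
#' @param config A [cohort_config()].
#' @param subject Subject parameters from [draw_subject_params()] (or a
#'   hand-built list with the same fields).
#' @return Object of class `latent_trajectory`: tibble with `time_h`, `C`
#'   (CSF, ug/L), `Q` (quotient), `B` (blood, ug/L), plus the subject
#'   parameters in attributes.
#' @export
simulate_latent <- function(config, subject) {
  dt <- config$euler_step_h
  tt <- seq(0, config$duration_h, by = dt)
  lam_c <- log(2) / config$csf_decay_halflife_h
  lam_q <- log(2) / config$qa_decay_halflife_h
  lam_e <- log(2) / config$blood_halflife_h

  C <- subject$csf_amp * exp(-lam_c * tt)
  if (config$qa_rise_halflife_h > 0) {
    lam_r <- log(2) / config$qa_rise_halflife_h
    shape <- exp(-lam_q * tt) - exp(-lam_r * tt)
    mx <- max(shape)
    shape <- if (mx > 0) shape / mx else shape * 0
  } else {
    shape <- exp(-lam_q * tt)
  }
  Q <- config$qa_base + subject$qa_excess * shape

  # delayed inputs: zero while the delayed time is negative
  lag_value <- function(x, delay) {
    shift <- round(delay / dt)
    if (shift == 0) return(x)
    c(rep(0, min(shift, length(x))), head(x, -shift))
  }
  in_bbb <- config$k_bbb * lag_value(Q * C, config$delay_bbb_h)
  in_alt <- config$k_alt * lag_value(C, config$delay_alt_h)

  B <- numeric(length(tt))
  B[1] <- config$blood_baseline
  for (i in seq_len(length(tt) - 1)) {
    B[i + 1] <- B[i] + dt * (in_bbb[i] + in_alt[i] - lam_e * B[i])
    if (!is.finite(B[i + 1]))
      stop_bbb(sprintf(
        "non-finite blood state at t = %.1f h (k_bbb = %g, k_alt = %g, blood_halflife_h = %g, euler_step_h = %g)",
        tt[i + 1], config$k_bbb, config$k_alt, config$blood_halflife_h, dt))
  }
  out <- tibble::tibble(time_h = tt, C = C, Q = Q, B = B)
  structure(out, class = c("latent_trajectory", class(out)),
            subject = subject, config = config)
}

#' Observe a latent trajectory on the sampling schedule
#'
#' CSF biomarker observations are means of the latent CSF concentration over
#' the preceding pooling window (the continuous-drainage pool); blood
#' observations are point values; albumin is sampled on its own sparser
#' schedule and decomposed into CSF and blood albumin so that the quotient
#' can be recomputed downstream.  All observations carry multiplicative
#' lognormal assay noise with unit mean.  Multitrauma subjects receive an
#' additive extracranial blood bump over the first hours when
#' `extracranial_spike = "on"`.
#'
#' @param latent A `latent_trajectory`.
#' @param config The [cohort_config()] used to simulate it.
#' @return Measurement tibble (canonical units) for one subject.
#' @export
observe_cohort <- function(latent, config) {
  subject <- attr(latent, "subject")
  if (max(latent$time_h) < config$duration_h)
    stop_bbb("latent trajectory does not cover the follow-up window")
  t0 <- subject$admission_offset_h
  bm_times <- seq(t0, config$duration_h, by = config$biomarker_interval_h)
  alb_times <- seq(t0, config$duration_h, by = config$albumin_interval_h)
  if (length(bm_times) == 0 || length(alb_times) == 0)
    stop_bbb("empty sampling schedule")

  interp <- function(col, times)
    approx(latent$time_h, latent[[col]], xout = times, rule = 2)$y
  pooled_csf <- vapply(bm_times, function(t) {
    w <- latent$time_h > t - config$csf_pool_window_h & latent$time_h <= t
    mean(latent$C[w])
  }, numeric(1))

  blood <- interp("B", bm_times)
  if (config$extracranial_spike == "on" && subject$multitrauma) {
    # decays with a 2 h half-life: negligible (<2%) beyond 12 h post trauma
    blood <- blood + config$spike_amp * 2^(-bm_times / 2)
  }
  qa <- interp("Q", alb_times)
  alb_blood <- subject$alb_blood * noise_factor(length(alb_times), config$noise_cv)
  alb_csf <- qa * subject$alb_blood * 1000 *
    noise_factor(length(alb_times), config$noise_cv)

  pre <- config$analyte_prefix
  dplyr::bind_rows(
    tibble::tibble(subject_id = subject$subject_id,
                   analyte = paste0(pre, "_CSF"), time_h = bm_times,
                   value = pooled_csf * noise_factor(length(bm_times), config$noise_cv),
                   unit = "ug/L"),
    tibble::tibble(subject_id = subject$subject_id,
                   analyte = paste0(pre, "_BLOOD"), time_h = bm_times,
                   value = blood * noise_factor(length(bm_times), config$noise_cv),
                   unit = "ug/L"),
    tibble::tibble(subject_id = subject$subject_id,
                   analyte = "ALB_CSF", time_h = alb_times,
                   value = alb_csf, unit = "mg/L"),
    tibble::tibble(subject_id = subject$subject_id,
                   analyte = "ALB_BLOOD", time_h = alb_times,
                   value = alb_blood, unit = "g/L")
  )
}

#' Simulate a full cohort
#'
#' @param config A [cohort_config()]; its `seed` (or the `seed` argument)
#'   seeds all randomness, making output tables reproducible.
#' @param seed Overrides `config$seed` when given.
#' @return List with `measurements` (long tibble over all subjects),
#'   `subjects` (synthetic demographics: id, disruption status, multitrauma,
#'   admission offset), and `latent_params` (per-subject true parameters).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%02d", seq_len(config$n_subjects))
  subs <- lapply(ids, function(id) draw_subject_params(config, id))
  meas <- dplyr::bind_rows(lapply(subs, function(s)
    observe_cohort(simulate_latent(config, s), config)))
  subjects <- tibble::tibble(
    subject_id = ids,
    disrupted = vapply(subs, `[[`, logical(1), "disrupted"),
    multitrauma = vapply(subs, `[[`, logical(1), "multitrauma"),
    admission_offset_h = vapply(subs, `[[`, numeric(1), "admission_offset_h")
  )
  list(measurements = meas, subjects = subjects, latent_params = subs,
       config = config)
}

#' Study-calibrated cohort profiles
#'
#' Two ready-made parameterisations of [cohort_config()] mirroring the
#' qualitative clearance signatures of the two classic brain biomarkers:
#'
#' * `"S100B_like"` -- barrier-dependent route only (`k_alt = 0`) with a
#'   12 h transport delay; barrier disruption maximal at trauma.  CSF:blood
#'   cross-correlation peaks one 12-h lag after CSF, as does Q_A:blood.
#' * `"NSE_like"` -- barrier-independent route only (`k_bbb = 0`) with a
#'   24 h delay, slower CSF decay, and a barrier disruption that builds up
#'   over the first day (disruption develops secondarily, after the
#'   immediate CSF release).  CSF:blood peaks at two lags while Q_A:blood
#'   peaks at lag 0.
#'
#' @param profile `"S100B_like"` or `"NSE_like"`.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_config()].
#' @return As [simulate_cohort()].
#' @export
make_study_like_cohort <- function(profile = c("S100B_like", "NSE_like"),
                                   n = 16, seed = 1, ...) {
  profile <- match.arg(profile)
  if (n < 2) stop_bbb("`n` must be >= 2")
  defaults <- if (profile == "S100B_like") {
    list(n_subjects = n, seed = seed, analyte_prefix = "S100B",
         csf_amp_mu = 30, csf_decay_halflife_h = 36,
         qa_decay_halflife_h = 72, qa_rise_halflife_h = 0,
         k_bbb = 0.5, k_alt = 0, delay_bbb_h = 12,
         blood_baseline = 0.02, spike_amp = 0.5)
  } else {
    list(n_subjects = n, seed = seed, analyte_prefix = "NSE",
         csf_amp_mu = 100, csf_decay_halflife_h = 48,
         qa_decay_halflife_h = 60, qa_rise_halflife_h = 18,
         k_bbb = 0, k_alt = 0.15, delay_alt_h = 24,
         blood_baseline = 5)
  }
  args <- utils::modifyList(defaults, list(...))
  cfg <- do.call(cohort_config, args)
  out <- simulate_cohort(cfg)
  out$profile <- profile
  out
}
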
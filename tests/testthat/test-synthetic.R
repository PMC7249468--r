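# Two-compartment synthetic cohort generator.

base_subject <- function(cfg, ...) {
  utils::modifyList(list(subject_id = "P01", csf_amp = cfg$csf_amp_mu,
                         disrupted = TRUE, qa_excess = cfg$qa_excess_mu,
                         admission_offset_h = 0, multitrauma = FALSE,
                         alb_blood = 40), list(...))
}

test_that("blood reduces to pure exponential elimination when both routes are off", {
  cfg <- cohort_config(k_bbb = 0, k_alt = 0, blood_halflife_h = 12,
                       blood_baseline = 0.5, euler_step_h = 0.05)
  lat <- simulate_latent(cfg, base_subject(cfg))
  lam_e <- log(2) / 12
  closed <- 0.5 * exp(-lam_e * lat$time_h)
  expect_lt(max(abs(lat$B - closed)) / max(closed), 0.01)
})

test_that("with no disruption and no alternative route blood stays at baseline decay", {
  cfg <- cohort_config(k_bbb = 0.5, k_alt = 0, qa_base = 0,
                       blood_halflife_h = 24, blood_baseline = 0.3,
                       euler_step_h = 0.05)
  s <- base_subject(cfg, disrupted = FALSE, qa_excess = 0)
  lat <- simulate_latent(cfg, s)
  closed <- 0.3 * exp(-log(2) / 24 * lat$time_h)
  expect_lt(max(abs(lat$B - closed)) / max(closed), 0.01)
})

test_that("halving the Euler step changes blood by less than 1% sup-norm", {
  cfg1 <- cohort_config()          # default step
  cfg2 <- cohort_config(euler_step_h = cfg1$euler_step_h / 2)
  s <- base_subject(cfg1)
  b1 <- simulate_latent(cfg1, s)
  b2 <- simulate_latent(cfg2, s)
  common <- intersect(b1$time_h, b2$time_h)
  d <- abs(b1$B[match(common, b1$time_h)] - b2$B[match(common, b2$time_h)])
  expect_lt(max(d) / max(b2$B), 0.01)
})

test_that("latent trajectories respect their invariants", {
  cfg <- cohort_config(seed = 4)
  set.seed(4)
  for (i in 1:5) {
    s <- draw_subject_params(cfg, paste0("P", i))
    lat <- simulate_latent(cfg, s)
    expect_true(all(lat$C >= 0) && all(lat$Q >= cfg$qa_base - 1e-12) &&
                  all(lat$B >= 0))
  }
})

test_that("barrier-route flux and blood correlate positively on the latent grid", {
  cfg <- cohort_config(k_bbb = 0.5, k_alt = 0, delay_bbb_h = 12)
  s <- base_subject(cfg)
  lat <- simulate_latent(cfg, s)
  shift <- round(12 / cfg$euler_step_h)
  flux <- c(rep(0, shift), head(lat$Q * lat$C, -shift))
  expect_gt(stats::cor(lat$B, flux), 0)
})

test_that("noiseless observation equals the latent trajectory", {
  cfg <- cohort_config(noise_cv = 0, extracranial_spike = "off",
                       admission_offset_range_h = c(0, 0))
  s <- base_subject(cfg)
  lat <- simulate_latent(cfg, s)
  obs <- observe_cohort(lat, cfg)
  blood <- obs[obs$analyte == "S100B_BLOOD", ]
  expect_equal(blood$value,
               approx(lat$time_h, lat$B, xout = blood$time_h)$y)
  csf <- obs[obs$analyte == "S100B_CSF", ]
  pooled <- vapply(csf$time_h, function(t) {
    w <- lat$time_h > t - cfg$csf_pool_window_h & lat$time_h <= t
    mean(lat$C[w])
  }, numeric(1))
  expect_equal(csf$value, pooled)
  # and the recomputed albumin quotient recovers the latent quotient exactly
  qa <- derive_qa(obs)
  qa <- qa[qa$analyte == "QA", ]
  expect_equal(qa$value, approx(lat$time_h, lat$Q, xout = qa$time_h)$y,
               tolerance = 1e-12)
})

test_that("identical seeds give byte-identical cohorts", {
  a <- simulate_cohort(cohort_config(n_subjects = 3), seed = 11)
  b <- simulate_cohort(cohort_config(n_subjects = 3), seed = 11)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$subjects, b$subjects)
  c_ <- simulate_cohort(cohort_config(n_subjects = 3), seed = 12)
  expect_false(identical(a$measurements, c_$measurements))
})

test_that("a 12-h schedule over one week yields 15 CSF observations", {
  cfg <- cohort_config(biomarker_interval_h = 12,
                       admission_offset_range_h = c(0, 0))
  s <- base_subject(cfg)
  obs <- observe_cohort(simulate_latent(cfg, s), cfg)
  expect_equal(sum(obs$analyte == "S100B_CSF"), 15)
  expect_equal(range(obs$time_h[obs$analyte == "S100B_CSF"]), c(0, 168))
})

test_that("observed concentrations are positive and increasing k_bbb never lowers blood", {
  cfg0 <- cohort_config(k_bbb = 0.2, seed = 3)
  cfg1 <- cohort_config(k_bbb = 0.6, seed = 3)
  a <- simulate_cohort(cfg0)
  b <- simulate_cohort(cfg1)
  expect_true(all(a$measurements$value > 0))
  mean_blood <- function(sim) mean(sim$measurements$value[
    sim$measurements$analyte == "S100B_BLOOD"])
  expect_gte(mean_blood(b), mean_blood(a))
})

test_that("half the subjects are disrupted on average", {
  cfg <- cohort_config(n_subjects = 16, qa_disrupted_prob = 0.5)
  counts <- vapply(1:12, function(s)
    sum(simulate_cohort(cfg, seed = s)$subjects$disrupted), numeric(1))
  expect_gt(mean(counts), 5.5)
  expect_lt(mean(counts), 10.5)
})

test_that("multitrauma extracranial spike raises early blood S100B only", {
  cfg_on <- cohort_config(extracranial_spike = "on", noise_cv = 0,
                          admission_offset_range_h = c(2, 2))
  s <- base_subject(cfg_on, multitrauma = TRUE, admission_offset_h = 2)
  lat <- simulate_latent(cfg_on, s)
  obs_on <- observe_cohort(lat, cfg_on)
  cfg_off <- cohort_config(extracranial_spike = "off", noise_cv = 0,
                           admission_offset_range_h = c(2, 2))
  obs_off <- observe_cohort(lat, cfg_off)
  d <- obs_on$value[obs_on$analyte == "S100B_BLOOD"] -
    obs_off$value[obs_off$analyte == "S100B_BLOOD"]
  t <- obs_on$time_h[obs_on$analyte == "S100B_BLOOD"]
  expect_gt(d[[which(t == 2)]], 0.1)
  expect_lt(max(abs(d[t > 12])), 0.02 * cfg_on$spike_amp)
})

test_that("invalid configurations are refused", {
  expect_error(cohort_config(euler_step_h = 2), "<= 1 hour")
  expect_error(cohort_config(qa_disrupted_prob = 1.5), "probability")
  expect_error(cohort_config(csf_decay_halflife_h = -1), "positive")
  expect_error(make_study_like_cohort("S100B_like", n = 1), ">= 2")
})
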
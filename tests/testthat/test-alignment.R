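# Interpolation, complete cases, log10, early-window exclusion, lag binning.

mk <- function(subject, analyte, t, v) {
  tibble::tibble(subject_id = subject, analyte = analyte, time_h = t,
                 value = v, unit = "ug/L")
}

test_that("linear interpolation hits midpoints, observed points and no further", {
  m <- mk("P1", "S100B_CSF", c(0, 12), c(1, 3))
  g <- interpolate_to_grid(m, grid_spacing_h = 6)
  got <- g[g$analyte == "S100B_CSF", ]
  expect_equal(got$value[got$time_h == 6], 2)
  expect_equal(got$provenance[got$time_h == 6], "interpolated")
  expect_equal(got$value[got$time_h == 0], 1)
  expect_equal(got$provenance[got$time_h == 0], "observed")
  # no extrapolation beyond the observed span
  m2 <- dplyr::bind_rows(m, mk("P1", "NSE_CSF", c(0, 24), c(5, 5)))
  g2 <- interpolate_to_grid(m2, 6)
  s100 <- g2[g2$analyte == "S100B_CSF", ]
  expect_true(all(is.na(s100$value[s100$time_h > 12])))
  expect_true(all(s100$provenance[s100$time_h > 12] == "missing"))
})

test_that("constant series interpolate to the constant; single points stay points", {
  m <- mk("P1", "S100B_CSF", c(0, 7, 18), c(4, 4, 4))
  g <- interpolate_to_grid(m, 6)
  vals <- g$value[g$analyte == "S100B_CSF" & g$time_h <= 18]
  expect_true(all(vals == 4))
  m1 <- mk("P1", "S100B_CSF", 12, 9)
  g1 <- interpolate_to_grid(m1, 6)
  expect_equal(g1$value[g1$time_h == 12], 9)
  expect_equal(g1$provenance[g1$time_h == 12], "observed")
  expect_true(all(is.na(g1$value[g1$time_h != 12])))
})

test_that("interpolation values are bounded by neighbouring observations", {
  set.seed(8)
  m <- mk("P1", "S100B_CSF", sort(c(0, runif(6, 1, 47), 48)),
          exp(rnorm(8)))
  g <- interpolate_to_grid(m, 6)
  v <- g$value[!is.na(g$value)]
  expect_true(all(v >= min(m$value) - 1e-12 & v <= max(m$value) + 1e-12))
})

test_that("conflicting duplicate measurements are an error", {
  m <- mk("P1", "S100B_CSF", c(6, 6), c(1, 2))
  expect_error(interpolate_to_grid(m), "duplicate")
  m_ok <- mk("P1", "S100B_CSF", c(6, 6, 12), c(1, 1, 2))
  expect_silent(g <- interpolate_to_grid(m_ok))
})

test_that("complete-case filtering drops exactly the incomplete rows", {
  m <- dplyr::bind_rows(
    mk("P1", "S100B_CSF", c(0, 6, 12), c(1, 2, 3)),
    mk("P1", "QA", c(0, 6), c(0.005, 0.006)))
  g <- interpolate_to_grid(m, 6)
  w <- complete_cases(g, c("S100B_CSF", "QA"))
  expect_equal(nrow(w), 2)          # t = 12 lacks QA
  counts <- attr(w, "case_counts")
  expect_equal(unname(counts["input"] - counts["retained"]),
               unname(counts["dropped"]))
  # no missing cells -> identity
  w2 <- complete_cases(g, "S100B_CSF")
  expect_equal(nrow(w2), 3)
  # every row missing the required analyte -> empty result with a warning
  expect_warning(w3 <- complete_cases(g[g$time_h == 12, ], "QA"),
                 "every row")
  expect_equal(nrow(w3), 0)
})

test_that("log10 transform is elementwise with an exact round trip", {
  m <- mk("P1", "S100B_CSF", c(0, 6, 12), c(1, 100, 42))
  g <- interpolate_to_grid(m, 6)
  gl <- log10_transform(g, "S100B_CSF")
  expect_equal(gl$value[gl$time_h == 0], 0)
  expect_equal(gl$value[gl$time_h == 6], 2)
  expect_equal(10^gl$value[gl$time_h == 12], 42, tolerance = 1e-12)
  expect_identical(gl$provenance, g$provenance)
  g$value[2] <- -1
  expect_error(log10_transform(g, "S100B_CSF"), "non-positive")
})

test_that("early-window exclusion is half-open and idempotent", {
  m <- mk("P1", "S100B_BLOOD", c(0, 6, 12, 18), 1:4)
  g <- interpolate_to_grid(m, 6)
  e1 <- exclude_early_window(g, "S100B_BLOOD", 12)
  kept <- e1$time_h[e1$analyte == "S100B_BLOOD"]
  expect_setequal(kept, c(12, 18))
  expect_identical(exclude_early_window(e1, "S100B_BLOOD", 12), e1)
  expect_identical(exclude_early_window(g, "S100B_BLOOD", 0), g)
})

test_that("lag binning is half-open with within-bin averaging", {
  m <- mk("P1", "S100B_CSF", c(1, 11, 12), c(2, 4, 10))
  l <- bin_to_lags(m)
  expect_equal(l$value[l$lag == 0], 3)     # mean of 2 and 4
  expect_equal(l$value[l$lag == 1], 10)    # t = 12 belongs to bin 1
  expect_equal(nrow(bin_to_lags(m[0, ])), 0)
  # a single observation is its own bin mean; constants are conserved
  mc <- mk("P2", "NSE_CSF", c(3, 15, 27), c(7, 7, 7))
  lc <- bin_to_lags(mc)
  expect_true(all(lc$value == 7))
})

test_that("early-window exclusion stabilises the Q_A term under extracranial spikes", {
  fit_qa <- function(meas, exclude) {
    m <- derive_qa(meas)
    grid <- interpolate_to_grid(m, 6)
    grid <- log10_transform(grid, c("S100B_CSF", "S100B_BLOOD", "QA"))
    if (exclude) grid <- exclude_early_window(grid, "S100B_BLOOD", 12)
    wide <- complete_cases(grid, c("S100B_CSF", "S100B_BLOOD", "QA"))
    md <- tibble::tibble(subject_id = wide$subject_id, time_h = wide$time_h,
                         y = wide$S100B_BLOOD, csf = wide$S100B_CSF,
                         qa = wide$QA,
                         time_d = wide$time_h / 24 - mean(wide$time_h / 24))
    md$time_d2 <- md$time_d^2
    f <- fit_marginal_gls(y ~ time_d + time_d2 + csf + qa, md, p = 1, q = 1)
    f$beta$estimate[f$beta$term == "qa"]
  }
  devs <- vapply(1:4, function(s) {
    on <- make_study_like_cohort("S100B_like", n = 16, seed = s,
                                 extracranial_spike = "on",
                                 multitrauma_prob = 0.6, spike_amp = 1.5)
    off <- make_study_like_cohort("S100B_like", n = 16, seed = s,
                                  extracranial_spike = "off",
                                  multitrauma_prob = 0.6)
    ref <- fit_qa(off$measurements, exclude = FALSE)  # spike-free reference
    c(abs(fit_qa(on$measurements, TRUE) - ref),
      abs(fit_qa(on$measurements, FALSE) - ref))
  }, numeric(2))
  # excluding the contaminated window moves the barrier coefficient less
  # from its spike-free value than keeping it does, on average
  expect_lt(mean(devs[1, ]), mean(devs[2, ]))
})
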
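# ARMA correlation structure, GLS and mixed clearance models, KPSS, AIC
# selection and the inference helpers.

test_that("ARMA correlation matrices match their closed forms", {
  expect_equal(arma_correlation_matrix(arma_spec(0, 0), 5), diag(5))
  M <- arma_correlation_matrix(arma_spec(1, 0, phi = 0.5), 6)
  expect_equal(M[1, ], 0.5^(0:5))
  phi <- 0.976; theta <- 0.563
  M11 <- arma_correlation_matrix(arma_spec(1, 1, phi, theta), 4)
  rho1 <- (1 + phi * theta) * (phi + theta) / (1 + theta^2 + 2 * phi * theta)
  expect_equal(M11[1, 2], rho1, tolerance = 1e-12)
  expect_equal(M11[1, 3], phi * rho1, tolerance = 1e-12)
  expect_error(arma_spec(1, 0, phi = 1.2), "non-stationary")
  expect_error(arma_spec(0, 1, theta = -1.3), "non-invertible")
})

test_that("ARMA(1,1) lag-1 correlation agrees with a long simulated recursion", {
  phi <- 0.976; theta <- 0.563
  rho1 <- arma_correlation_matrix(arma_spec(1, 1, phi, theta), 2)[1, 2]
  set.seed(9)
  n <- 2e6
  e <- rnorm(n + 1)
  innov <- e[-1] + theta * e[-(n + 1)]
  x <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  x <- x[-(1:1000)]
  expect_equal(rho1, stats::cor(x[-1], x[-length(x)]), tolerance = 1e-3)
})

test_that("every stationary spec from the unconstrained map is positive definite", {
  set.seed(19)
  for (i in 1:25) {
    p <- sample(0:4, 1); q <- sample(0:4, 1)
    if (p + q == 0) next
    sp <- bbbclear:::arma_from_unconstrained(rnorm(p + q, 0, 1.5), p, q)
    M <- arma_correlation_matrix(sp, 12)
    expect_silent(chol(M))
    expect_equal(diag(M), rep(1, 12))
  }
})

test_that("GLS with white-noise orders reduces to ordinary least squares", {
  d <- gen_panel(phi = 0, theta = 0, seed = 2)
  f <- fit_marginal_gls(y ~ I(time_h / 10) + x, d, p = 0, q = 0,
                        method = "ML")
  o <- lm(y ~ I(time_h / 10) + x, data = d)
  expect_equal(f$beta$estimate, unname(coef(o)), tolerance = 1e-8)
  expect_equal(f$loglik, as.numeric(stats::logLik(o)), tolerance = 1e-8)
})

test_that("the fitted ARMA(1,1) optimum dominates a profile-likelihood grid", {
  set.seed(5)
  d <- dplyr::bind_rows(lapply(1:2, function(i) {
    e <- as.numeric(arima.sim(list(ar = 0.6), 6, sd = 0.5))
    x <- rnorm(6)
    tibble::tibble(subject_id = as.character(i), time_h = 1:6, x = x,
                   y = 1 + 0.3 * x + e)
  }))
  f <- fit_marginal_gls(y ~ x, d, p = 1, q = 1, method = "ML")
  des <- bbbclear:::prepare_design(y ~ x, d, "subject_id", "time_h", NULL)
  grid_ll <- -Inf
  for (phi in seq(-0.95, 0.95, length.out = 21))
    for (th in seq(-0.95, 0.95, length.out = 21)) {
      pf <- bbbclear:::profile_fit(des, arma_spec(1, 1, phi, th),
                                   NULL, NULL, "ML")
      if (!is.null(pf)) grid_ll <- max(grid_ll, pf$ll)
    }
  expect_gte(f$loglik, grid_ll - 1e-4)
})

test_that("GLS agrees with the independent nlme implementation", {
  skip_if_not_installed("nlme")
  d <- gen_panel(seed = 42)
  f <- fit_marginal_gls(y ~ I(time_h / 10) + x, d, p = 1, q = 1,
                        method = "REML")
  g <- nlme::gls(y ~ I(time_h / 10) + x, data = d,
                 correlation = nlme::corARMA(form = ~ time_h | subject_id,
                                             p = 1, q = 1),
                 method = "REML")
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-3)
  expect_equal(f$beta$estimate, unname(coef(g)), tolerance = 1e-4)
})

test_that("mixed model with zero random effects equals the marginal model", {
  d <- gen_panel(nsub = 6, nt = 12, seed = 6)
  gls <- fit_marginal_gls(y ~ x, d, p = 1, q = 1)
  lmm0 <- fit_linear_mixed(y ~ x, d, p = 1, q = 1,
                           psi_fixed = matrix(0, 2, 2))
  expect_equal(lmm0$loglik, gls$loglik, tolerance = 1e-6)
  expect_equal(lmm0$beta$estimate, gls$beta$estimate, tolerance = 1e-6)
})

test_that("random-intercept variance is recovered from simulated data", {
  set.seed(11)
  nsub <- 200
  d <- dplyr::bind_rows(lapply(seq_len(nsub), function(i) {
    b <- rnorm(1, 0, 1)
    tibble::tibble(subject_id = sprintf("S%03d", i), time_h = 1:6,
                   y = b + rnorm(6, 0, 0.5))
  }))
  f <- fit_linear_mixed(y ~ 1, d, p = 0, q = 0, random_slope = FALSE)
  mc_se <- sqrt(2 / nsub)  # relative sampling error of a variance at n subjects
  expect_lt(abs(f$psi[1, 1] - 1), 3 * mc_se)
  expect_lt(abs(f$sigma2 - 0.25) / 0.25, 0.15)
  expect_false(f$boundary_psi)
})

test_that("boundary random-effect covariances are flagged, not hidden", {
  d <- gen_panel(nsub = 8, nt = 15, phi = 0.6, theta = 0.2, seed = 7)
  f <- fit_linear_mixed(y ~ x, d, random_time = "time_h", p = 1, q = 1)
  expect_type(f$boundary_psi, "logical")
  if (f$boundary_psi) {
    ev <- eigen(f$psi, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(min(ev) / max(f$sigma2, 1e-12), 1e-6)
  }
})

test_that("KPSS statistic matches a hand computation at truncation zero", {
  x <- c(1, 3, 2, 5, 4, 6, 3, 7)
  e <- x - mean(x); S <- cumsum(e)
  manual <- sum(S^2) / (length(x)^2 * mean(e^2))
  k <- kpss_test(x, lag_truncation = 0)
  expect_equal(k$statistic, manual, tolerance = 1e-12)
  expect_error(kpss_test(rep(2, 10)), "constant")
  expect_error(kpss_test(rnorm(5)), "too short")
})

test_that("KPSS is calibrated: ~5% size on white noise, high power on random walks", {
  set.seed(20)
  size <- mean(replicate(200, kpss_test(rnorm(200))$verdict == "rejected"))
  expect_gt(size, 0.01)
  expect_lt(size, 0.11)
  power <- mean(replicate(100,
    kpss_test(cumsum(rnorm(200)))$verdict == "rejected"))
  expect_gte(power, 0.85)
})

test_that("AIC selection prefers the generating structure", {
  gen <- function(phi, th, seed) {
    set.seed(seed)
    dplyr::bind_rows(lapply(1:8, function(i) {
      e <- if (phi == 0) rnorm(25, 0, 0.5) else
        as.numeric(arima.sim(list(ar = phi, ma = th), 25, sd = 0.5))
      x <- rnorm(25)
      tibble::tibble(subject_id = as.character(i), time_h = 1:25, x = x,
                     y = 1 + 0.3 * x + e)
    }))
  }
  cands <- data.frame(p = c(0, 1, 1), q = c(0, 0, 1))
  picks <- vapply(1:5, function(s) {
    sel <- select_arma_by_aic(y ~ x, gen(0.8, 0.4, s), orders = cands,
                              method = "ML")
    paste0(sel$best$arma$p, sel$best$arma$q)
  }, character(1))
  expect_gte(sum(picks == "11"), 4)
  # independent errors: white noise beats ARMA(1,1) on average AIC
  diffs <- vapply(1:5, function(s) {
    sel <- select_arma_by_aic(y ~ x, gen(0, 0, s + 50),
                              orders = data.frame(p = c(0, 1), q = c(0, 1)),
                              method = "ML")
    sel$table$aic[2] - sel$table$aic[1]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  # a single candidate is returned unconditionally
  one <- select_arma_by_aic(y ~ x, gen(0, 0, 99),
                            orders = data.frame(p = 1, q = 0), method = "ML")
  expect_equal(c(one$best$arma$p, one$best$arma$q), c(1, 0))
})

test_that("the AIC identity holds exactly on every fit", {
  d <- gen_panel(nsub = 4, nt = 10, seed = 23)
  for (f in list(
    fit_marginal_gls(y ~ x, d, p = 0, q = 0, method = "ML"),
    fit_marginal_gls(y ~ x, d, p = 1, q = 1, method = "REML"),
    fit_linear_mixed(y ~ x, d, p = 0, q = 0, random_slope = FALSE))) {
    expect_identical(f$aic, -2 * f$loglik + 2 * f$n_par)
  }
})

test_that("ML likelihood never decreases along a nesting chain", {
  d <- gen_panel(nsub = 5, nt = 12, seed = 24)
  f1 <- fit_marginal_gls(y ~ 1, d, p = 0, q = 0, method = "ML")
  f2 <- fit_marginal_gls(y ~ x, d, p = 0, q = 0, method = "ML")
  f3 <- fit_marginal_gls(y ~ x, d, p = 1, q = 0, method = "ML")
  f4 <- fit_marginal_gls(y ~ x, d, p = 1, q = 1, method = "ML")
  lls <- c(f1$loglik, f2$loglik, f3$loglik, f4$loglik)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("likelihood-ratio tests behave at the null and under signal", {
  d <- gen_panel(nsub = 5, nt = 12, seed = 25)
  f <- fit_marginal_gls(y ~ x, d, p = 0, q = 0, method = "ML")
  same <- compare_models_lrt(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # power: across replicates the strong covariate is detected essentially
  # always, while the null chain above stays at 0
  strong_p <- vapply(1:20, function(s) {
    ds <- gen_panel(nsub = 5, nt = 12, beta = c(1, 0.5, -0.8), seed = 500 + s)
    g0 <- fit_marginal_gls(y ~ 1, ds, p = 0, q = 0, method = "ML")
    g1 <- fit_marginal_gls(y ~ x, ds, p = 0, q = 0, method = "ML")
    compare_models_lrt(g0, g1)$p
  }, numeric(1))
  expect_gte(mean(strong_p <= 0.05), 0.95)
  fr <- fit_marginal_gls(y ~ x, d, p = 0, q = 0, method = "REML")
  fr0 <- fit_marginal_gls(y ~ 1, d, p = 0, q = 0, method = "REML")
  expect_error(compare_models_lrt(fr0, fr), "REML")
})

test_that("sequential F tests pick up the strong covariate", {
  d <- gen_panel(nsub = 6, nt = 15, seed = 26)
  f <- fit_marginal_gls(y ~ I(time_h / 10) + x, d, p = 1, q = 1)
  a <- anova_type1(f)
  expect_equal(a$term, c("I(time_h/10)", "x"))
  expect_lt(a$p[a$term == "x"], 1e-6)
})

test_that("Satterthwaite df reduces to classical answers", {
  set.seed(27)
  d0 <- tibble::tibble(subject_id = "A", time_h = 1:30, y = rnorm(30))
  fi <- fit_marginal_gls(y ~ 1, d0, p = 0, q = 0)
  si <- satterthwaite_df(fi, "(Intercept)")
  expect_equal(si$df, 29, tolerance = 1e-4)
  expect_false(si$fallback)
  # balanced one-way random intercept: between-subject df ~ subjects - 1
  db <- dplyr::bind_rows(lapply(1:10, function(i) {
    b <- rnorm(1)
    tibble::tibble(subject_id = sprintf("S%02d", i), time_h = 1:8,
                   y = b + rnorm(8, 0, 0.5))
  }))
  fb <- fit_linear_mixed(y ~ 1, db, p = 0, q = 0, random_slope = FALSE)
  sb <- satterthwaite_df(fb, "(Intercept)")
  expect_lt(abs(sb$df - 9) / 9, 0.10)
  # large-n: Satterthwaite p converges to the normal approximation
  dl <- gen_panel(nsub = 30, nt = 20, phi = 0, theta = 0, seed = 28)
  fl <- fit_marginal_gls(y ~ x, dl, p = 0, q = 0)
  sl <- satterthwaite_df(fl, "x")
  p_norm <- 2 * pnorm(-abs(sl$t))
  expect_lt(abs(sl$p - p_norm), 1e-3)
})

test_that("diagnostics flag injected outlier subjects and perfect fits", {
  d <- gen_panel(nsub = 8, nt = 15, phi = 0, theta = 0, seed = 29)
  d$y[d$subject_id == "S03"] <- d$y[d$subject_id == "S03"] * 10
  f <- fit_marginal_gls(y ~ x, d, p = 0, q = 0)
  dg <- model_diagnostics(f)
  expect_true("S03" %in% dg$flagged_subjects)
  # perfect linear data: fitted-observed correlation 1
  dp <- tibble::tibble(subject_id = rep("A", 10), time_h = 1:10,
                       x = 1:10, y = 2 + 3 * (1:10))
  fp <- fit_marginal_gls(y ~ x, dp, p = 0, q = 0)
  expect_equal(model_diagnostics(fp)$fitted_observed_cor, 1, tolerance = 1e-8)
  # white-noise residual ACF stays inside +-2/sqrt(n) bands ~95% of the time
  dw <- gen_panel(nsub = 6, nt = 40, phi = 0, theta = 0, seed = 30)
  fw <- fit_marginal_gls(y ~ I(time_h / 10) + x, dw, p = 0, q = 0)
  dgw <- model_diagnostics(fw, acf_lag_max = 10)
  frac_in <- mean(unlist(lapply(dgw$acf, function(a)
    abs(a$acf[-1]) <= 2 / sqrt(a$n))))
  expect_gt(frac_in, 0.85)
})

test_that("published clearance coefficients are recovered from simulated data", {
  beta <- c(-1.13, -3.82, 0.665, 0.0247, -0.0676)  # simulation ground truth
  phi <- 0.976; theta <- 0.563
  set.seed(21)
  d <- dplyr::bind_rows(lapply(1:50, function(i) {
    nt <- 28
    t <- (seq_len(nt) * 6) / 168
    csf <- cumsum(rnorm(nt, 0, 0.3)) + rnorm(1, 1, 0.5)
    qa <- cumsum(rnorm(nt, 0, 0.2)) - 2.3
    e <- as.numeric(arima.sim(list(ar = phi, ma = theta), nt, sd = 0.15))
    tibble::tibble(subject_id = as.character(i), time_h = seq_len(nt) * 6,
                   t = t, t2 = t^2, csf = csf, qa = qa,
                   y = beta[1] + beta[2] * t + beta[3] * t^2 +
                     beta[4] * csf + beta[5] * qa + e)
  }))
  f <- fit_marginal_gls(y ~ t + t2 + csf + qa, d, p = 1, q = 1)
  z <- (f$beta$estimate - beta) / f$beta$se
  expect_true(all(abs(z) < 3))
  expect_lt(abs(f$arma$phi - phi), 0.02)
  expect_lt(abs(f$arma$theta - theta), 0.1)
  ci <- f$arma_ci
  expect_true(ci$ci_low[ci$coef == "phi1"] < phi &&
                phi < ci$ci_high[ci$coef == "phi1"])
})
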
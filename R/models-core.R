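# Shared likelihood engine for the clearance models: marginal GLS with
# ARMA(p,q) errors and the linear mixed model with random intercept+slope
# plus ARMA(p,q) residual correlation.  beta and sigma^2 are profiled out of
# the Gaussian (restricted) likelihood; the remaining variance parameters
# are maximised numerically on unconstrained transforms (tanh/partial
# autocorrelations for the ARMA region, log-Cholesky for the random-effect
# covariance).

# Assemble response, design matrix, subject blocks and integer grid indices.
prepare_design <- function(formula, data, subject, time, grid_spacing_h) {
  vars <- all.vars(formula)
  need <- unique(c(vars, subject, time))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop_bbb("columns absent from data: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars]), ]
  d <- d[order(d[[subject]], d[[time]]), ]
  if (nrow(d) == 0) stop_bbb("no complete cases")
  mf <- model.frame(formula, d)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop_bbb("singular fixed-effect design")
  y <- model.response(mf)
  subj <- as.character(d[[subject]])
  tvec <- d[[time]]
  if (is.null(grid_spacing_h)) {
    dt <- unlist(tapply(tvec, subj, function(v) diff(sort(unique(v)))))
    grid_spacing_h <- if (length(dt) > 0) min(dt) else 1
  }
  gidx <- as.integer(round(tvec / grid_spacing_h))
  blocks <- split(seq_len(nrow(d)), subj)
  list(X = X, y = y, subject = subj, time = tvec, gidx = gidx,
       blocks = blocks, formula = formula, data = d,
       grid_spacing_h = grid_spacing_h, assign = attr(X, "assign"))
}

# ARMA correlation blocks on each subject's (possibly gappy) grid indices.
arma_blocks <- function(spec, des) {
  max_span <- max(vapply(des$blocks, function(ix)
    diff(range(des$gidx[ix])), numeric(1)), 1)
  rho <- if (spec$p == 0 && spec$q == 0) c(1, rep(0, max_span))
         else as.numeric(ARMAacf(ar = spec$phi, ma = spec$theta,
                                 lag.max = max_span))
  lapply(des$blocks, function(ix) {
    g <- des$gidx[ix]
    M <- rho[abs(outer(g, g, "-")) + 1L]
    matrix(M, length(g), length(g))
  })
}

# Random-effect design per subject: [1] (intercept only) or [1, time].
lmm_z_blocks <- function(des, random_time, random_slope = TRUE) {
  lapply(des$blocks, function(ix) {
    if (random_slope) cbind(1, des$data[[random_time]][ix])
    else matrix(1, length(ix), 1)
  })
}

# log-Cholesky parameterisation of the r x r relative random-effect
# covariance Psi* = Psi / sigma^2 (r(r+1)/2 parameters; exp on the
# diagonal keeps the factor, and hence Psi*, in the PSD cone).
psi_from_par <- function(par, r = 2) {
  L <- matrix(0, r, r)
  diag(L) <- exp(par[seq_len(r)])
  if (r > 1) L[lower.tri(L)] <- par[-seq_len(r)]
  L %*% t(L)
}

# Profiled (restricted) log-likelihood and fitted quantities for given
# variance parameters.  psi_star = NULL gives the marginal GLS model.
profile_fit <- function(des, spec, psi_star = NULL, Z = NULL,
                        method = "REML") {
  R <- arma_blocks(spec, des)
  n <- length(des$y)
  p <- ncol(des$X)
  logdet <- 0
  Xw <- matrix(0, n, p)
  yw <- numeric(n)
  for (b in seq_along(des$blocks)) {
    ix <- des$blocks[[b]]
    W <- R[[b]]
    if (!is.null(psi_star)) W <- W + Z[[b]] %*% psi_star %*% t(Z[[b]])
    L <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    logdet <- logdet + 2 * sum(log(diag(L)))
    Xw[ix, ] <- backsolve(L, des$X[ix, , drop = FALSE], transpose = TRUE)
    yw[ix] <- backsolve(L, des$y[ix], transpose = TRUE)
  }
  qrX <- qr(Xw)
  beta <- qr.coef(qrX, yw)
  rss <- sum(qr.resid(qrX, yw)^2)
  XtX <- crossprod(Xw)
  if (method == "REML") {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet +
                    determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  }
  ll_other <- if (method == "REML") {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + logdet + n)
  } else {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + logdet +
              determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  list(ll = ll, ll_ml = if (method == "ML") ll else ll_other,
       ll_reml = if (method == "REML") ll else ll_other,
       beta = beta, sigma2 = sigma2, rss = rss,
       cov_beta = sigma2 * solve(XtX), Xw = Xw, yw = yw, n = n, p = p)
}

# Deterministic multi-start set for the unconstrained variance parameters.
multi_starts <- function(npar, kind, n_psi = 0) {
  if (npar == 0) return(list(numeric(0)))
  base <- list(rep(0, npar), rep(0.5, npar), rep(-0.5, npar))
  if (kind == "linear_mixed" && n_psi > 0) {
    s4 <- rep(0, npar); s4[seq_len(n_psi)] <- -2
    s5 <- rep(0.3, npar); s5[seq_len(n_psi)] <- -1
    c(base, list(s4, s5))
  } else {
    c(base, list(c(1, rep(0, npar - 1))),
      list(c(rep(0, npar - 1), 0.5)))
  }
}

fit_engine <- function(des, p, q, kind, method, random_time = NULL,
                       psi_fixed = NULL, random_slope = TRUE,
                       control = list()) {
  has_psi <- kind == "linear_mixed" && is.null(psi_fixed)
  r_ranef <- if (kind != "linear_mixed") 0L else if (random_slope) 2L else 1L
  n_psi <- if (has_psi) as.integer(r_ranef * (r_ranef + 1) / 2) else 0L
  npar <- n_psi + p + q
  Z <- if (kind == "linear_mixed")
    lmm_z_blocks(des, random_time, random_slope) else NULL
  if (kind == "linear_mixed" &&
      length(des$blocks) < 3 && is.null(psi_fixed))
    stop_bbb("need >= 3 subjects to estimate the random-effect covariance")

  objective <- function(u) {
    spec <- tryCatch(arma_from_unconstrained(u[n_psi + seq_len(p + q)], p, q),
                     error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    psi <- if (has_psi) psi_from_par(u[seq_len(n_psi)], r_ranef)
           else if (!is.null(psi_fixed)) psi_fixed
           else NULL
    pf <- profile_fit(des, spec, psi, Z, method)
    if (is.null(pf) || !is.finite(pf$ll)) return(1e10)
    -pf$ll
  }

  if (npar == 0) {
    best <- list(par = numeric(0), value = objective(numeric(0)),
                 convergence = 0)
  } else {
    best <- NULL
    nm_method <- if (npar == 1) "BFGS" else "Nelder-Mead"
    for (s in multi_starts(npar, kind, n_psi)) {
      o <- tryCatch(suppressWarnings(
        optim(s, objective, method = nm_method,
              control = list(maxit = control$maxit %||% 750))),
        error = function(e) NULL)
      if (is.null(o)) next
      o2 <- tryCatch(optim(o$par, objective, method = "BFGS",
                           control = list(maxit = 200)),
                     error = function(e) o)
      cand <- if (!is.null(o2) && o2$value <= o$value) o2 else o
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    if (is.null(best) || best$value >= 1e10)
      stop_bbb("model fit failed to converge for ARMA(", p, ",", q, ")")
  }

  u <- best$par
  spec <- arma_from_unconstrained(u[n_psi + seq_len(p + q)], p, q)
  psi_star <- if (has_psi) psi_from_par(u[seq_len(n_psi)], r_ranef)
              else if (!is.null(psi_fixed)) psi_fixed else NULL
  pf <- profile_fit(des, spec, psi_star, Z, method)

  # CIs for the ARMA coefficients from the observed information on the
  # unconstrained scale, mapped back by the delta method.
  arma_ci <- NULL
  if (p + q > 0) {
    H <- tryCatch(optimHess(u, objective), error = function(e) NULL)
    vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      coefs_of <- function(uu) {
        s <- arma_from_unconstrained(uu[n_psi + seq_len(p + q)], p, q)
        c(s$phi, s$theta)
      }
      est <- coefs_of(u)
      J <- vapply(seq_along(u), function(i) {
        e <- rep(0, length(u)); e[i] <- 1e-5
        (coefs_of(u + e) - coefs_of(u - e)) / 2e-5
      }, numeric(p + q))
      J <- matrix(J, nrow = p + q)
      se <- sqrt(pmax(diag(J %*% vc %*% t(J)), 0))
      arma_ci <- tibble::tibble(
        coef = c(if (p > 0) paste0("phi", seq_len(p)),
                 if (q > 0) paste0("theta", seq_len(q))),
        estimate = est, se = se,
        ci_low = est - qnorm(0.975) * se,
        ci_high = est + qnorm(0.975) * se)
    }
  }

  n_varpar <- npar + 1L  # + sigma^2
  k <- ncol(des$X) + n_varpar
  ll <- pf$ll
  boundary <- FALSE
  psi <- NULL
  if (!is.null(psi_star)) {
    psi <- psi_star * pf$sigma2
    ev <- eigen(psi_star, symmetric = TRUE, only.values = TRUE)$values
    boundary <- any(ev < 1e-8)
  }

  se <- sqrt(diag(pf$cov_beta))
  tval <- pf$beta / se
  df_res <- pf$n - pf$p
  beta_tab <- tibble::tibble(
    term = colnames(des$X), estimate = unname(pf$beta), se = se,
    df = df_res, t = unname(tval),
    p = 2 * pt(-abs(unname(tval)), df_res))

  structure(list(
    kind = kind, formula = des$formula, beta = beta_tab,
    sigma2 = pf$sigma2, arma = spec, arma_ci = arma_ci,
    psi = psi, psi_star = psi_star, boundary_psi = boundary,
    loglik = ll, loglik_ml = pf$ll_ml, loglik_reml = pf$ll_reml,
    aic = -2 * ll + 2 * k, n_par = k, method = method,
    n_obs = pf$n, n_subjects = length(des$blocks),
    cov_beta = pf$cov_beta, par_u = u, n_psi_par = n_psi,
    convergence = best$convergence %||% 0, r_ranef = r_ranef,
    des = des, Z = Z, random_time = random_time, psi_fixed = psi_fixed
  ), class = "bbb_model_fit")
}

#' @export
print.bbb_model_fit <- function(x, ...) {
  cat(sprintf("%s clearance model (%s), ARMA(%d,%d) errors\n",
              if (x$kind == "marginal_gls") "Marginal GLS" else "Linear mixed",
              x$method, x$arma$p, x$arma$q))
  cat(sprintf("  %d observations, %d subjects; logLik %.3f, AIC %.2f\n",
              x$n_obs, x$n_subjects, x$loglik, x$aic))
  if (isTRUE(x$boundary_psi))
    cat("  NOTE: random-effect covariance on the boundary (not positive",
        "definite); the marginal model is recommended.\n")
  print(as.data.frame(x$beta), digits = 4, row.names = FALSE)
  if (!is.null(x$arma_ci)) {
    cat("  correlation structure:\n")
    print(as.data.frame(x$arma_ci), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Marginal GLS clearance model with ARMA errors
#'
#' Generalized-least-squares regression with a block-diagonal
#' within-subject ARMA(p,q) correlation structure ("marginal model"): beta
#' and the residual variance are profiled out of the (restricted)
#' likelihood and the ARMA coefficients are maximised numerically on an
#' unconstrained transform of the stationarity region.  The intended
#' response is a log10 blood biomarker with time, time squared, the log10
#' CSF level and the log10 albumin quotient as regressors, but any fixed
#' formula is accepted.
#'
#' @param formula Fixed-effect formula (response on the left).
#' @param data Data frame, one row per subject x grid time; rows within a
#'   subject must lie on a regular grid (gaps are allowed and handled
#'   through the grid index).
#' @param subject,time Column names of the subject identifier and the time
#'   variable used for grid indexing (hours).
#' @param p,q ARMA orders of the within-subject correlation.
#' @param method `"REML"` (default, for variance-structure comparison) or
#'   `"ML"` (for fixed-effect likelihood-ratio tests).
#' @param grid_spacing_h Grid spacing; inferred from the data when `NULL`.
#' @param control List; `maxit` caps the Nelder-Mead iterations.
#' @return Object of class `bbb_model_fit`.
#' @export
fit_marginal_gls <- function(formula, data, subject = "subject_id",
                             time = "time_h", p = 1, q = 1,
                             method = c("REML", "ML"),
                             grid_spacing_h = NULL, control = list()) {
  method <- match.arg(method)
  des <- prepare_design(formula, data, subject, time, grid_spacing_h)
  fit_engine(des, p, q, "marginal_gls", method, control = control)
}

#' Linear mixed clearance model with ARMA errors
#'
#' Random intercept and random slope (in the `random_time` variable) per
#' subject, ARMA(p,q) residual correlation: the marginal covariance of
#' subject i is `V_i = Z_i Psi Z_i' + sigma^2 R_i(phi, theta)`, with Psi
#' parameterised through its Cholesky factor so the optimiser cannot leave
#' the positive-semidefinite cone.  A Psi estimate on the cone's boundary
#' (not positive definite) is flagged and the marginal model recommended,
#' rather than silently accepted.
#'
#' @inheritParams fit_marginal_gls
#' @param random_time Column used as the random-slope covariate (defaults
#'   to `time`).
#' @param psi_fixed Optional fixed value for the *relative* random-effect
#'   covariance Psi/sigma^2 (e.g. `matrix(0, 2, 2)` collapses the model to
#'   the marginal GLS fit).
#' @return Object of class `bbb_model_fit` with `psi` (random-effect
#'   covariance) and `boundary_psi`.
#' @export
fit_linear_mixed <- function(formula, data, subject = "subject_id",
                             time = "time_h", random_time = NULL,
                             p = 1, q = 1, method = c("REML", "ML"),
                             grid_spacing_h = NULL, psi_fixed = NULL,
                             random_slope = TRUE, control = list()) {
  method <- match.arg(method)
  des <- prepare_design(formula, data, subject, time, grid_spacing_h)
  fit_engine(des, p, q, "linear_mixed", method,
             random_time = random_time %||% time, psi_fixed = psi_fixed,
             random_slope = random_slope, control = control)
}

#' Select the ARMA correlation structure by AIC
#'
#' Fits one model per candidate (p, q) order pair and returns the converged
#' candidate with the smallest AIC, ties broken toward fewer parameters.
#' The default candidate grid is all orders with p, q in 0..4 (25
#' combinations).
#'
#' @inheritParams fit_marginal_gls
#' @param orders Two-column matrix or data frame of candidate (p, q) pairs.
#' @param kind `"marginal_gls"` or `"linear_mixed"`.
#' @param ... Passed to the fitting function.
#' @return List with `best` (the winning `bbb_model_fit`), `table` (AIC per
#'   candidate, failures recorded as `NA`), and `failures`.
#' @export
select_arma_by_aic <- function(formula, data, orders = NULL,
                               kind = c("marginal_gls", "linear_mixed"),
                               ...) {
  kind <- match.arg(kind)
  if (is.null(orders))
    orders <- expand.grid(p = 0:4, q = 0:4)
  orders <- as.data.frame(orders)
  names(orders) <- c("p", "q")
  if (nrow(orders) < 1) stop_bbb("no candidate orders")
  fitter <- if (kind == "marginal_gls") fit_marginal_gls else fit_linear_mixed
  fits <- vector("list", nrow(orders))
  aics <- rep(NA_real_, nrow(orders))
  msgs <- rep(NA_character_, nrow(orders))
  for (i in seq_len(nrow(orders))) {
    f <- tryCatch(fitter(formula, data, p = orders$p[i], q = orders$q[i], ...),
                  error = function(e) e)
    if (inherits(f, "error")) msgs[i] <- conditionMessage(f)
    else { fits[[i]] <- f; aics[i] <- f$aic }
  }
  if (all(is.na(aics))) stop_bbb("every candidate ARMA structure failed")
  tab <- tibble::tibble(p = orders$p, q = orders$q, aic = aics,
                        n_par = orders$p + orders$q, error = msgs)
  ok <- which(!is.na(aics))
  best_i <- ok[order(aics[ok], orders$p[ok] + orders$q[ok])][1]
  list(best = fits[[best_i]], table = tab,
       failures = tab[!is.na(tab$error), ])
}
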
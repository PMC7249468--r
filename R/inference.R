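# Model comparison and tests: likelihood-ratio tests between nested fits,
# sequential (type I) F tests, and Satterthwaite effective degrees of
# freedom for fixed-effect contrasts.

#' Likelihood-ratio test between nested fits
#'
#' `2 * (logLik_full - logLik_reduced)` against chi-square with the
#' parameter-count difference as degrees of freedom.  Fixed-effect
#' comparisons must use ML fits; random/covariance-structure comparisons
#' use REML fits with identical fixed parts (both conventions are checked).
#'
#' @param reduced,full Nested `bbb_model_fit`s on the same response rows.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
compare_models_lrt <- function(reduced, full) {
  stopifnot(inherits(reduced, "bbb_model_fit"), inherits(full, "bbb_model_fit"))
  if (reduced$n_obs != full$n_obs)
    stop_bbb("fits use different numbers of observations; not nested")
  if (reduced$method != full$method)
    stop_bbb("fits use different estimation criteria")
  same_fixed <- identical(colnames(reduced$des$X), colnames(full$des$X))
  if (reduced$method == "REML" && !same_fixed)
    stop_bbb("REML likelihoods are only comparable with identical fixed effects; refit with method = \"ML\"")
  if (full$n_par < reduced$n_par)
    stop_bbb("`full` has fewer parameters than `reduced`; not nested")
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  df <- full$n_par - reduced$n_par
  p <- if (df == 0) as.numeric(stat <= 1e-8) else
    pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p = p)
}

#' Sequential (type I) F tests for the fixed terms of a fit
#'
#' Whitens the response and design with the fitted covariance and computes
#' the classical sequential analysis of variance in term entry order.
#'
#' @param fit A `bbb_model_fit`.
#' @return Tibble with one row per fixed term: `term`, `df`, `ss`, `f`, `p`.
#' @export
anova_type1 <- function(fit) {
  des <- fit$des
  pf <- profile_fit(des, fit$arma, fit$psi_star, fit$Z, fit$method)
  Xw <- pf$Xw; yw <- pf$yw
  asgn <- des$assign
  terms_lab <- attr(terms(des$formula), "term.labels")
  has_int <- attr(terms(des$formula), "intercept") == 1
  groups <- sort(unique(asgn))
  rss <- numeric(length(groups))
  dfs <- integer(length(groups))
  cols <- integer(0)
  for (i in seq_along(groups)) {
    cols <- c(cols, which(asgn == groups[i]))
    q <- qr(Xw[, cols, drop = FALSE])
    rss[i] <- sum(qr.resid(q, yw)^2)
    dfs[i] <- sum(asgn == groups[i])
  }
  df_res <- pf$n - ncol(Xw)
  ms_res <- rss[length(rss)] / df_res
  seq_ss <- -diff(c(sum(yw^2), rss))
  labels <- if (has_int) c("(Intercept)", terms_lab) else terms_lab
  out <- tibble::tibble(
    term = labels, df = dfs, ss = seq_ss,
    f = (seq_ss / dfs) / ms_res,
    p = pf((seq_ss / dfs) / ms_res, dfs, df_res, lower.tail = FALSE))
  if (has_int) out <- out[-1, ]
  out
}

# Negative restricted log-likelihood as a function of the *full*
# unconstrained variance parameter vector (psi chol, arma transforms,
# log sigma^2) -- unprofiled in sigma^2, for observed-information purposes.
varpar_objective <- function(fit) {
  des <- fit$des
  p <- fit$arma$p; q <- fit$arma$q
  n_psi <- fit$n_psi_par
  Z <- fit$Z
  psi_fixed <- fit$psi_fixed
  n <- fit$n_obs; pX <- ncol(des$X)
  function(w) {
    u <- w[seq_len(n_psi + p + q)]
    sigma2 <- exp(w[length(w)])
    spec <- tryCatch(arma_from_unconstrained(u[n_psi + seq_len(p + q)], p, q),
                     error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    psi <- if (n_psi > 0) psi_from_par(u[seq_len(n_psi)], fit$r_ranef)
           else psi_fixed
    R <- arma_blocks(spec, des)
    logdet <- 0
    Xw <- matrix(0, n, pX); yw <- numeric(n)
    for (b in seq_along(des$blocks)) {
      ix <- des$blocks[[b]]
      W <- R[[b]]
      if (!is.null(psi)) W <- W + Z[[b]] %*% psi %*% t(Z[[b]])
      L <- tryCatch(chol(W), error = function(e) NULL)
      if (is.null(L)) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(L)))
      Xw[ix, ] <- backsolve(L, des$X[ix, , drop = FALSE], transpose = TRUE)
      yw[ix] <- backsolve(L, des$y[ix], transpose = TRUE)
    }
    qrX <- qr(Xw)
    rss <- sum(qr.resid(qrX, yw)^2)
    XtX <- crossprod(Xw)
    ll <- -0.5 * ((n - pX) * log(2 * pi * sigma2) + logdet +
                    determinant(XtX, logarithm = TRUE)$modulus[1] +
                    rss / sigma2)
    -ll
  }
}

# Var(c' beta_hat) as a function of the full variance parameter vector.
contrast_variance_fn <- function(fit, contrast) {
  des <- fit$des
  p <- fit$arma$p; q <- fit$arma$q
  n_psi <- fit$n_psi_par
  Z <- fit$Z
  psi_fixed <- fit$psi_fixed
  pX <- ncol(des$X)
  function(w) {
    u <- w[seq_len(n_psi + p + q)]
    sigma2 <- exp(w[length(w)])
    spec <- arma_from_unconstrained(u[n_psi + seq_len(p + q)], p, q)
    psi <- if (n_psi > 0) psi_from_par(u[seq_len(n_psi)], fit$r_ranef)
           else psi_fixed
    R <- arma_blocks(spec, des)
    XtX <- matrix(0, pX, pX)
    for (b in seq_along(des$blocks)) {
      ix <- des$blocks[[b]]
      W <- R[[b]]
      if (!is.null(psi)) W <- W + Z[[b]] %*% psi %*% t(Z[[b]])
      L <- chol(W)
      Xw <- backsolve(L, des$X[ix, , drop = FALSE], transpose = TRUE)
      XtX <- XtX + crossprod(Xw)
    }
    sigma2 * drop(t(contrast) %*% solve(XtX, contrast))
  }
}

#' Satterthwaite effective degrees of freedom for a contrast
#'
#' `df = 2 * Var(c'beta)^2 / (g' A g)` where `g` is the gradient of the
#' contrast variance in the variance parameters and `A` their asymptotic
#' covariance (inverse observed information of the restricted likelihood,
#' obtained numerically).  When the information matrix is unusable the
#' residual degrees of freedom `n - rank(X)` are returned with
#' `fallback = TRUE`.
#'
#' @param fit A `bbb_model_fit`.
#' @param contrast Numeric contrast vector over the fixed effects, or the
#'   name of a single coefficient.
#' @return List with `estimate`, `se`, `df`, `t`, `p`, `fallback`.
#' @export
satterthwaite_df <- function(fit, contrast) {
  if (is.character(contrast)) {
    idx <- match(contrast, fit$beta$term)
    if (is.na(idx)) stop_bbb("unknown coefficient: ", contrast)
    cvec <- as.numeric(fit$beta$term == contrast)
  } else cvec <- as.numeric(contrast)
  est <- sum(cvec * fit$beta$estimate)
  w_hat <- c(fit$par_u, log(fit$sigma2))
  vfun <- contrast_variance_fn(fit, cvec)
  v_hat <- vfun(w_hat)
  df_fallback <- fit$n_obs - ncol(fit$des$X)
  df <- df_fallback; fallback <- TRUE
  cand <- tryCatch({
    A <- solve(num_hess(varpar_objective(fit), w_hat))
    g <- num_grad(vfun, w_hat)
    denom <- drop(t(g) %*% A %*% g)
    if (is.finite(denom) && denom > 0) 2 * v_hat^2 / denom else NA_real_
  }, error = function(e) NA_real_)
  if (is.finite(cand) && cand > 0) { df <- cand; fallback <- FALSE }
  se <- sqrt(v_hat)
  tval <- est / se
  list(estimate = est, se = se, df = df, t = tval,
       p = 2 * pt(-abs(tval), df), fallback = fallback)
}
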
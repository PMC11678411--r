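# --- parameter vector packing -------------------------------------------
# The estimated parameters of a fit are packed into an unconstrained
# vector theta: log typical values, covariate coefficients as-is, log
# random-effect SDs, log error parameters. Shared by the importance-
# sampling likelihood closure and the finite-difference Hessian.

.theta_spec <- function(fit) {
  frame <- fit$frame
  entries <- list()
  for (p in frame$phi_names) {
    cf <- frame$coef_fixed[[p]]
    cn <- names(fit$gamma[[p]])
    for (j in seq_along(cn)) {
      if (cf[j]) next
      entries[[length(entries) + 1L]] <- list(
        name = if (cn[j] == "(Intercept)") p else cn[j],
        type = if (cn[j] == "(Intercept)") "logpop" else "beta",
        p = p, coef = cn[j])
    }
  }
  for (j in seq_len(frame$d)) {
    if (!frame$omega_est[j]) next
    p <- frame$phi_names[j]
    entries[[length(entries) + 1L]] <- list(
      name = paste0("omega_", p), type = "logomega", p = p)
  }
  if (!frame$error_fixed) {
    for (e in switch(frame$error_kind, constant = "a", proportional = "b",
                     combined = c("a", "b"))) {
      entries[[length(entries) + 1L]] <- list(name = e, type = "logerr", p = e)
    }
  }
  entries
}

.theta_pack <- function(fit, spec = .theta_spec(fit)) {
  vapply(spec, function(en) {
    switch(en$type,
           logpop = fit$gamma[[en$p]][[en$coef]],
           beta = fit$gamma[[en$p]][[en$coef]],
           logomega = log(fit$omega[[en$p]]),
           logerr = log(fit$err[[en$p]]))
  }, numeric(1))
}

.theta_unpack <- function(fit, spec, theta) {
  gamma <- fit$gamma; omega <- fit$omega; err <- fit$err
  for (j in seq_along(spec)) {
    en <- spec[[j]]
    switch(en$type,
           logpop = { gamma[[en$p]][[en$coef]] <- theta[j] },
           beta = { gamma[[en$p]][[en$coef]] <- theta[j] },
           logomega = { omega[[en$p]] <- exp(theta[j]) },
           logerr = { err[[en$p]] <- exp(theta[j]) })
  }
  list(gamma = gamma, omega = omega, err = err)
}

# --- importance sampling -------------------------------------------------
# Heavy-tailed proposal: multivariate t (df 5) centred at each subject's
# Laplace posterior mode with the Laplace covariance. Returns a closure so
# the same draws (common random numbers) can be re-evaluated at perturbed
# population parameters for finite-difference standard errors.

.is_cache <- function(fit, n_samples, seed, df) {
  frame <- fit$frame
  n <- frame$n; d <- frame$d; S <- n_samples
  set.seed(seed)
  mode <- fit$ebe$mode
  Rts <- lapply(fit$ebe$cov, function(cv) t(chol(cv)))
  logdet <- vapply(fit$ebe$cov, function(cv) determinant(cv)$modulus[1],
                   numeric(1))
  lq <- matrix(0, n, S)
  preds <- matrix(0, frame$n_obs, S)
  phis <- array(0, c(n, d, S))
  lq_const <- lgamma((df + d) / 2) - lgamma(df / 2) -
    (d / 2) * log(df * pi) - 0.5 * logdet
  for (s in seq_len(S)) {
    z <- matrix(stats::rnorm(n * d), n, d)
    wch <- stats::rchisq(n, df)
    scale <- sqrt(df / wch)
    phi <- mode
    for (i in seq_len(n)) {
      phi[i, ] <- mode[i, ] + drop(Rts[[i]] %*% z[i, ]) * scale[i]
    }
    quad <- rowSums(z^2) * df / wch
    lq[, s] <- lq_const - ((df + d) / 2) * log1p(quad / df)
    phis[, , s] <- phi
    preds[, s] <- .predict_phi(frame, phi)
  }
  resid <- matrix(frame$y, frame$n_obs, S) - preds
  list(frame = frame, n_samples = S, df = df, phis = phis, preds = preds,
       resid = resid, lq = lq)
}

.is_eval <- function(fit, cache, pars) {
  frame <- cache$frame
  n <- frame$n; d <- frame$d; S <- cache$n_samples
  mu <- .frame_mu(frame, pars$gamma)
  sdv <- .err_sd(cache$preds, pars$err, frame$error_kind)
  llobs <- stats::dnorm(cache$resid, 0, sdv, log = TRUE)
  llobs[!is.finite(llobs)] <- -1e10
  ll_y <- rowsum(llobs, frame$isubj_obs, reorder = TRUE)
  lprior <- matrix(0, n, S)
  for (j in seq_len(d)) {
    lprior <- lprior + stats::dnorm(cache$phis[, j, ], mu[, j],
                                    pars$omega[j], log = TRUE)
  }
  lw <- ll_y + lprior - cache$lq
  lmax <- apply(lw, 1, max)
  w <- exp(lw - lmax)
  sw <- rowSums(w)
  ll_i <- lmax + log(sw) - log(S)
  se_i <- apply(w, 1, stats::sd) / (sqrt(S) * sw / S)
  ess <- sw^2 / rowSums(w^2)
  list(ll = sum(ll_i), ll_i = ll_i, mc_se = sqrt(sum(se_i^2)), ess = ess)
}

.likelihood_result <- function(ll, fit, method, mc_se = NA_real_,
                               ess_fraction = NA_real_) {
  P <- fit$n_params
  ofv <- -2 * ll
  structure(list(ofv = ofv, aic = ofv + 2 * P,
                 bic = ofv + P * log(fit$frame$n_obs),
                 mc_se_ofv = 2 * mc_se, n_params = P,
                 n_obs = fit$frame$n_obs, method = method,
                 ess_fraction = ess_fraction,
                 low_ess = is.finite(ess_fraction) && ess_fraction < 0.05),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("OFV %.3f  AIC %.3f  BIC %.3f  (%s, P=%d, N=%d)\n",
              x$ofv, x$aic, x$bic, x$method, x$n_params, x$n_obs))
  if (is.finite(x$mc_se_ofv)) cat(sprintf("Monte-Carlo SE of OFV: %.3f\n", x$mc_se_ofv))
  if (isTRUE(x$low_ess)) cat("warning: effective sample size below 5% of draws\n")
  invisible(x)
}

#' Marginal likelihood by importance sampling
#'
#' Per-subject marginal likelihoods are estimated by importance sampling
#' with a multivariate t proposal (default 5 degrees of freedom) centred
#' at each subject's Laplace posterior mode with the Laplace covariance.
#' OFV = -2 sum log L_i; AIC = OFV + 2P and BIC = OFV + P log(N_obs) where
#' P counts the estimated parameters and N_obs the observations. A result
#' whose mean effective sample size falls below 5\% of the draws carries a
#' warning flag.
#'
#' @param fit a `saem_fit`
#' @param n_samples importance samples per subject
#' @param seed RNG seed (common random numbers: the same seed gives
#'   comparable OFVs across nested models)
#' @param df proposal degrees of freedom
#' @return a `likelihood_result` with elements `ofv`, `aic`, `bic`,
#'   `mc_se_ofv`, `method`, `ess_fraction`
#' @export
loglik_is <- function(fit, n_samples = 1000, seed = fit$seed + 1e6, df = 5) {
  stopifnot(inherits(fit, "saem_fit"))
  cache <- .is_cache(fit, n_samples, seed, df)
  ev <- .is_eval(fit, cache, list(gamma = fit$gamma, omega = fit$omega,
                                  err = fit$err))
  .likelihood_result(ev$ll, fit, "importance_sampling", mc_se = ev$mc_se,
                     ess_fraction = mean(ev$ess) / n_samples)
}

# deterministic-function-of-theta closure over fixed draws (CRN)
.loglik_is_closure <- function(fit, n_samples = 500, seed = fit$seed + 1e6,
                               df = 5) {
  cache <- .is_cache(fit, n_samples, seed, df)
  spec <- .theta_spec(fit)
  function(theta) {
    pars <- .theta_unpack(fit, spec, theta)
    .is_eval(fit, cache, pars)$ll
  }
}

#' Marginal likelihood by adaptive Gauss-Hermite quadrature
#'
#' Deterministic tensor-product quadrature adapted per subject (centred at
#' the Laplace posterior mode, scaled by its covariance). Supports at most
#' two random effects; serves as the brute-force oracle against which the
#' importance-sampling estimator is validated.
#'
#' @param fit a `saem_fit` with at most 2 random effects
#' @param nodes Gauss-Hermite nodes per dimension
#' @return a `likelihood_result`
#' @export
loglik_agq <- function(fit, nodes = 32) {
  stopifnot(inherits(fit, "saem_fit"))
  frame <- fit$frame
  d <- frame$d
  if (d > 2) {
    stop_gabapk("adaptive quadrature supports at most 2 random effects",
                class = "gabapk_unsupported_error")
  }
  gh <- pracma::gaussHermite(nodes)
  if (d == 1) {
    zgrid <- matrix(gh$x, ncol = 1)
    lw_gh <- log(gh$w)
  } else {
    zgrid <- as.matrix(expand.grid(gh$x, gh$x))
    lw_gh <- log(as.vector(outer(gh$w, gh$w)))
  }
  mu <- .frame_mu(frame, fit$gamma)
  ll <- 0
  for (i in seq_len(frame$n)) {
    m <- fit$ebe$mode[i, ]
    R <- chol(fit$ebe$cov[[i]])
    phik <- sweep(zgrid %*% (sqrt(2) * R), 2, m, `+`)
    yi <- frame$y[frame$isubj_obs == i]
    g <- vapply(seq_len(nrow(phik)), function(k) {
      psi <- .phi_to_psi_one(frame, phik[k, ], i)
      pred <- .predict_one(frame, psi, i)
      sdv <- .err_sd(pred, fit$err, frame$error_kind)
      sum(stats::dnorm(yi, pred, sdv, log = TRUE)) +
        sum(stats::dnorm(phik[k, ], mu[i, ], fit$omega, log = TRUE))
    }, numeric(1))
    ll_i <- log_sum_exp(g + rowSums(zgrid^2) + lw_gh) +
      (d / 2) * log(2) + sum(log(diag(R)))
    ll <- ll + ll_i
  }
  .likelihood_result(ll, fit, "quadrature")
}

#' Standard errors by finite differences of the importance-sampled
#' log-likelihood
#'
#' Central finite differences of the marginal log-likelihood (evaluated
#' with common random numbers so the Monte-Carlo noise cancels across
#' perturbations) give the observed Fisher information; its inverse gives
#' the variance of the estimates. Log-scale parameters are mapped back by
#' the delta method. If the information matrix is not positive definite
#' the affected parameters are flagged and no SE is fabricated. Fixed
#' parameters carry no SE and do not appear.
#'
#' @param fit a `saem_fit`
#' @param n_samples importance samples per subject
#' @param seed RNG seed for the common draws
#' @param h relative finite-difference step
#' @return data.frame with columns parameter, estimate, se, rse_pct, flagged
#' @export
standard_errors <- function(fit, n_samples = 500, seed = fit$seed + 1e6,
                            h = 1e-3) {
  stopifnot(inherits(fit, "saem_fit"))
  spec <- .theta_spec(fit)
  theta0 <- .theta_pack(fit, spec)
  P <- length(theta0)
  f <- .loglik_is_closure(fit, n_samples, seed)
  hh <- h * pmax(abs(theta0), 1)
  H <- matrix(NA_real_, P, P)
  for (a in seq_len(P)) {
    ea <- replace(numeric(P), a, hh[a])
    fpa <- f(theta0 + ea); fma <- f(theta0 - ea)
    f0 <- if (a == 1) f(theta0) else f0
    H[a, a] <- (fpa - 2 * f0 + fma) / hh[a]^2
    if (a < P) for (b in (a + 1):P) {
      eb <- replace(numeric(P), b, hh[b])
      H[a, b] <- H[b, a] <-
        (f(theta0 + ea + eb) - f(theta0 + ea - eb) -
           f(theta0 - ea + eb) + f(theta0 - ea - eb)) / (4 * hh[a] * hh[b])
    }
  }
  info <- -H  # observed information on the theta scale
  se_theta <- rep(NA_real_, P)
  flagged <- rep(FALSE, P)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    # salvage parameter-wise what is salvageable, flag the rest
    dg <- diag(info)
    ok <- is.finite(dg) & dg > 0
    se_theta[ok] <- 1 / sqrt(dg[ok])
    flagged[] <- TRUE
  } else {
    se_theta <- sqrt(diag(vc))
  }
  est <- vapply(seq_len(P), function(j) {
    if (spec[[j]]$type == "beta") theta0[j] else exp(theta0[j])
  }, numeric(1))
  se <- vapply(seq_len(P), function(j) {
    if (spec[[j]]$type == "beta") se_theta[j] else se_theta[j] * est[j]
  }, numeric(1))
  data.frame(parameter = vapply(spec, `[[`, "", "name"),
             estimate = est, se = se,
             rse_pct = 100 * se / pmax(abs(est), 1e-12),
             flagged = flagged, row.names = NULL)
}
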
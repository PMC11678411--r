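# Internal fitting representation: a "model frame" flattens a pk_dataset +
# pop_model into vectors sized for vectorised likelihood evaluation across
# all subjects at once. Observations are indexed 1..Nobs; every
# (observation, dose) pair becomes one triplet row with its time offset tau
# and bioavailability-scaled dose w = F(amt) * amt.

.build_frame <- function(dataset, model) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(model, "pop_model"))
  covtab <- covariate_table(dataset)
  n <- length(dataset$subjects)
  vals <- .pop_values(model)
  tlag <- vals[["tlag"]] %||% 0

  y <- numeric(0); isubj_obs <- integer(0); obs_time <- numeric(0)
  t_iobs <- integer(0); t_isubj <- integer(0)
  t_tau <- numeric(0); t_amt <- numeric(0)
  iobs0 <- 0L
  for (i in seq_len(n)) {
    s <- dataset$subjects[[i]]
    no <- nrow(s$observations); nd <- nrow(s$doses)
    y <- c(y, s$observations$conc)
    isubj_obs <- c(isubj_obs, rep.int(i, no))
    obs_time <- c(obs_time, s$observations$time)
    t_iobs <- c(t_iobs, rep(iobs0 + seq_len(no), each = nd))
    t_isubj <- c(t_isubj, rep.int(i, no * nd))
    t_tau <- c(t_tau, as.vector(outer(s$doses$time, s$observations$time,
                                      function(d, o) o - d)) - tlag)
    t_amt <- c(t_amt, rep.int(s$doses$amount, no))
    iobs0 <- iobs0 + no
  }
  dmax <- if (model$bioavailability == "saturable") model$dmax else NULL
  w <- .dose_f(t_amt, dmax, model$d50) * t_amt

  # phi: parameters that carry a random effect or a covariate effect
  # an omega fixed at 0 means "no random effect": the parameter leaves phi
  om_fix <- model$omega_fixed
  om_fix <- om_fix[om_fix > 0]
  re_pars <- c(names(model$omega), names(om_fix))
  ce_pars <- vapply(model$covariate_effects, function(ce) ce$parameter,
                    character(1))
  phi_names <- intersect(c("V", "Cl", "ka", "ktr"), union(re_pars, ce_pars))
  if (!all(c("V", "Cl") %in% c(names(model$init), names(model$fixed)))) {
    stop_gabapk("model must define V and Cl", class = "gabapk_config_error")
  }

  # a parameter with a covariate effect but no stated random effect gets a
  # small fixed log-SD so the linear-Gaussian machinery applies
  omega_init <- numeric(0); omega_est <- logical(0)
  for (p in phi_names) {
    if (p %in% names(model$omega)) {
      omega_init[p] <- model$omega[[p]]; omega_est[p] <- TRUE
    } else if (p %in% names(om_fix)) {
      omega_init[p] <- om_fix[[p]]; omega_est[p] <- FALSE
    } else {
      omega_init[p] <- 0.05; omega_est[p] <- FALSE
    }
  }

  X <- list(); coef_init <- list(); coef_fixed <- list()
  effects <- list()
  for (p in phi_names) {
    cols <- list(`(Intercept)` = rep(1, n))
    ci <- c(log(vals[[p]]))
    cf <- c(!(p %in% names(model$init)))
    for (ce in model$covariate_effects) {
      if (ce$parameter != p) next
      xc <- .cov_column(ce, covtab)
      ce$ref <- ce$ref %||%
        (if (ce$type == "continuous") mean(covtab[[ce$covariate]]) else NULL)
      cols[[.beta_name(ce)]] <- if (ce$type == "continuous") {
        log(covtab[[ce$covariate]] / ce$ref)
      } else xc
      ci <- c(ci, ce$beta)
      cf <- c(cf, FALSE)
      effects[[.beta_name(ce)]] <- ce
    }
    X[[p]] <- do.call(cbind, cols)
    names(ci) <- colnames(X[[p]])
    coef_init[[p]] <- ci
    coef_fixed[[p]] <- cf
  }

  list(n = n, ids = names(dataset$subjects), covtab = covtab,
       y = y, isubj_obs = isubj_obs, obs_time = obs_time, n_obs = length(y),
       trip = list(iobs = t_iobs, isubj = t_isubj, tau = t_tau,
                   amount = t_amt, w = w),
       structural = model$structural, n_transit = model$n_transit,
       phi_names = phi_names, d = length(phi_names),
       X = X, coef_init = coef_init, coef_fixed = coef_fixed,
       XtX = lapply(X, crossprod),
       omega_init = omega_init, omega_est = omega_est,
       const = vals[setdiff(names(vals), phi_names)],
       error_kind = model$error$kind,
       error_init = c(a = model$error$a, b = model$error$b),
       error_fixed = model$error_fixed,
       effects = effects,
       model = model)
}

# transit-chain per-triplet contributions (equal-rate chain closed form)
.transit_terms <- function(tau, w, V, ke, ktr, n) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tau <- tau[pos]; w <- w[pos]
  V <- rep_len(V, length(out))[pos]
  ke <- rep_len(ke, length(out))[pos]
  ktr <- rep_len(ktr, length(out))[pos]
  lam <- ktr - ke
  val <- numeric(length(tau))
  big <- lam > 1e-8 * ktr
  if (any(big)) {
    i <- big
    val[i] <- w[i] * (ktr[i] / lam[i])^(n + 1) * exp(-ke[i] * tau[i]) *
      stats::pgamma(lam[i] * tau[i], n + 1) / V[i]
  }
  if (any(!big)) {
    i <- !big
    val[i] <- w[i] * ktr[i]^(n + 1) / factorial(n) * exp(-ke[i] * tau[i]) *
      .int_sn_exp(tau[i], lam[i], n) / V[i]
  }
  out[pos] <- val
  out
}

# I_n(tau, lam) = int_0^tau s^n exp(-lam s) ds, stable for lam <= 0 and
# near 0 (series); recursion I_m = (m I_{m-1} - tau^m e^{-lam tau}) / lam
.int_sn_exp <- function(tau, lam, n) {
  tiny <- abs(lam * tau) < 1e-8
  out <- numeric(length(tau))
  if (any(tiny)) {
    out[tiny] <- tau[tiny]^(n + 1) / (n + 1) *
      (1 - (n + 1) * lam[tiny] * tau[tiny] / (n + 2))
  }
  if (any(!tiny)) {
    tt <- tau[!tiny]; ll <- lam[!tiny]
    I <- -expm1(-ll * tt) / ll
    if (n >= 1) {
      for (m in 1:n) I <- (m * I - tt^m * exp(-ll * tt)) / ll
    }
    out[!tiny] <- I
  }
  out
}

# per-subject natural parameters from phi (log scale) + constants
.phi_to_psi <- function(frame, phi) {
  psi <- list()
  for (p in frame$phi_names) psi[[p]] <- exp(phi[, p])
  for (p in names(frame$const)) {
    if (!p %in% frame$phi_names) psi[[p]] <- rep(frame$const[[p]], frame$n)
  }
  psi
}

# per-observation predictions from per-subject natural parameters
.frame_predict <- function(frame, psi) {
  tr <- frame$trip
  V <- psi$V; ke <- psi$Cl / psi$V
  if (frame$structural == "first_order") {
    val <- .fo_terms(tr$tau, tr$w, V[tr$isubj], psi$ka[tr$isubj],
                     ke[tr$isubj])
  } else {
    val <- .transit_terms(tr$tau, tr$w, V[tr$isubj], ke[tr$isubj],
                          psi$ktr[tr$isubj], frame$n_transit)
  }
  as.vector(rowsum(val, tr$iobs, reorder = TRUE))
}

.predict_phi <- function(frame, phi) .frame_predict(frame, .phi_to_psi(frame, phi))

# residual SD with guards for use inside estimation (predictions may be
# negative under the constant-error model)
.err_sd <- function(pred, err, kind) {
  switch(kind,
         constant = rep_len(err[["a"]], length(pred)),
         proportional = pmax(err[["b"]] * abs(pred), 1e-8),
         combined = sqrt(err[["a"]]^2 + (err[["b"]] * pred)^2))
}

# per-subject observation log-likelihood given per-observation predictions
.ll_by_subject <- function(frame, preds, err) {
  sd <- .err_sd(preds, err, frame$error_kind)
  ll <- stats::dnorm(frame$y, mean = preds, sd = sd, log = TRUE)
  ll[!is.finite(ll)] <- -1e10
  as.vector(rowsum(ll, frame$isubj_obs, reorder = TRUE))
}

# prior mean matrix mu_i = X_i gamma
.frame_mu <- function(frame, gamma) {
  mu <- matrix(0, frame$n, frame$d,
               dimnames = list(NULL, frame$phi_names))
  for (p in frame$phi_names) mu[, p] <- drop(frame$X[[p]] %*% gamma[[p]])
  mu
}

# simulate one replicate of the design under given population parameters
.frame_simulate <- function(frame, gamma, omega, err) {
  mu <- .frame_mu(frame, gamma)
  eta <- matrix(stats::rnorm(frame$n * frame$d), frame$n, frame$d,
                dimnames = list(NULL, frame$phi_names))
  eta <- sweep(eta, 2, omega, `*`)
  phi <- mu + eta
  preds <- .predict_phi(frame, phi)
  sd <- .err_sd(preds, err, frame$error_kind)
  y <- preds + stats::rnorm(frame$n_obs) * sd
  list(y = y, eta = eta, phi = phi, preds = preds)
}
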
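#' SAEM estimation settings
#'
#' Controls the two-phase stochastic approximation schedule: `n_burnin`
#' exploratory iterations with step size 1 (and simulated annealing of the
#' variance parameters), then `n_smooth` smoothing iterations with step
#' size 1/(k - n_burnin). Each iteration runs `mh_reps` sweeps of three
#' Metropolis-Hastings kernels per subject (independent draw from the
#' population law, component-wise random walk, joint random walk) whose
#' proposal scales adapt towards `accept_target`.
#'
#' @param n_burnin burn-in (exploration) iterations, >= 1
#' @param n_smooth smoothing iterations, >= 1
#' @param mh_reps MH sweeps per iteration
#' @param anneal per-iteration lower bound factor on variance shrinkage
#'   during burn-in (simulated annealing); 0 disables
#' @param accept_target target MH acceptance rate for scale adaptation
#' @param omega_floor lower bound on estimated random-effect SDs
#' @export
saem_control <- function(n_burnin = 300, n_smooth = 200, mh_reps = 2,
                         anneal = 0.95, accept_target = 0.35,
                         omega_floor = 1e-3) {
  stopifnot(n_burnin >= 1, n_smooth >= 1, mh_reps >= 1,
            anneal >= 0, anneal < 1)
  structure(list(n_burnin = n_burnin, n_smooth = n_smooth,
                 mh_reps = mh_reps, anneal = anneal,
                 accept_target = accept_target, omega_floor = omega_floor),
            class = "saem_control")
}

# one MH sweep over all subjects (vectorised); returns updated state
.mh_sweep <- function(frame, phi, ll_y, mu, omega, err, scales, target) {
  n <- frame$n; d <- frame$d
  # kernel 1: independent proposal from the population law
  phi_star <- mu + sweep(matrix(stats::rnorm(n * d), n, d), 2, omega, `*`)
  colnames(phi_star) <- frame$phi_names
  ll_star <- .ll_by_subject(frame, .predict_phi(frame, phi_star), err)
  acc <- log(stats::runif(n)) < (ll_star - ll_y)
  phi[acc, ] <- phi_star[acc, , drop = FALSE]
  ll_y[acc] <- ll_star[acc]

  # kernel 2: component-wise random walk
  for (j in seq_len(d)) {
    phi_star <- phi
    phi_star[, j] <- phi[, j] + scales$comp[j] * omega[j] * stats::rnorm(n)
    ll_star <- .ll_by_subject(frame, .predict_phi(frame, phi_star), err)
    dprior <- stats::dnorm(phi_star[, j], mu[, j], omega[j], log = TRUE) -
      stats::dnorm(phi[, j], mu[, j], omega[j], log = TRUE)
    acc <- log(stats::runif(n)) < (ll_star - ll_y + dprior)
    phi[acc, j] <- phi_star[acc, j]
    ll_y[acc] <- ll_star[acc]
    rate <- mean(acc)
    scales$comp[j] <- min(20, max(0.05, scales$comp[j] *
                                    if (rate > target) 1.08 else 1 / 1.08))
  }

  # kernel 3: joint random walk
  phi_star <- phi + scales$joint *
    sweep(matrix(stats::rnorm(n * d), n, d), 2, omega, `*`)
  ll_star <- .ll_by_subject(frame, .predict_phi(frame, phi_star), err)
  dprior <- rowSums(stats::dnorm(phi_star, mu, rep(omega, each = n),
                                 log = TRUE) -
                    stats::dnorm(phi, mu, rep(omega, each = n), log = TRUE))
  acc <- log(stats::runif(n)) < (ll_star - ll_y + dprior)
  phi[acc, ] <- phi_star[acc, , drop = FALSE]
  ll_y[acc] <- ll_star[acc]
  rate <- mean(acc)
  scales$joint <- min(20, max(0.05, scales$joint *
                                if (rate > target) 1.08 else 1 / 1.08))

  list(phi = phi, ll_y = ll_y, scales = scales)
}

# restricted least squares for one parameter's coefficient vector: entries
# flagged fixed keep their value, the rest solve the normal equations
.mstep_coef <- function(XtX, xphi, coef, fixed) {
  est <- !fixed
  if (!any(est)) return(coef)
  rhs <- xphi[est]
  if (any(fixed)) {
    rhs <- rhs - XtX[est, fixed, drop = FALSE] %*% coef[fixed]
  }
  coef[est] <- drop(solve(XtX[est, est, drop = FALSE], rhs))
  coef
}

#' Fit a population PK model by SAEM
#'
#' Stochastic approximation EM for the nonlinear mixed-effects model: the
#' E-step samples individual log-parameters by Metropolis-Hastings under
#' the current population law; the stochastic approximation step updates
#' the sufficient statistics of the linear-Gaussian parameter model with
#' Robbins-Monro step sizes; the M-step solves them in closed form
#' (per-parameter least squares for typical values and covariate
#' coefficients, moment updates for the random-effect SDs and the constant
#' residual SD). Variances are annealed during burn-in so they cannot
#' collapse before the chain has explored. Identical seed, settings and
#' data give a bit-identical trajectory.
#'
#' @param dataset a [pk_dataset()]
#' @param model a [pop_model()] giving structure and initial values
#' @param control a [saem_control()]
#' @param seed integer seed; recorded in the result
#' @return an object of class `saem_fit`: estimates, full iteration
#'   trajectory, empirical Bayes machinery, and the updated model
#' @export
fit_saem <- function(dataset, model, control = saem_control(), seed = 1) {
  frame <- .build_frame(dataset, model)
  if (frame$d == 0) {
    stop_gabapk("degenerate fit: no parameter carries a random effect",
                class = "gabapk_config_error")
  }
  n_est_coef <- sum(vapply(frame$phi_names, function(p)
    sum(!frame$coef_fixed[[p]]), 0L))
  if (n_est_coef == 0 && !any(frame$omega_est) && frame$error_fixed) {
    stop_gabapk("degenerate fit: every parameter is fixed",
                class = "gabapk_config_error")
  }
  set.seed(seed)
  n <- frame$n; d <- frame$d
  K1 <- control$n_burnin; K2 <- control$n_smooth

  gamma <- frame$coef_init
  omega <- frame$omega_init
  err <- frame$error_init
  err_est <- if (frame$error_fixed) character(0) else
    switch(frame$error_kind, constant = "a", proportional = "b",
           combined = c("a", "b"))

  mu <- .frame_mu(frame, gamma)
  phi <- mu
  ll_y <- .ll_by_subject(frame, .predict_phi(frame, phi), err)
  scales <- list(comp = rep(1, d), joint = 0.5)

  # sufficient statistics (initialised on first iteration with step 1)
  s_xphi <- lapply(frame$phi_names, function(p) numeric(ncol(frame$X[[p]])))
  names(s_xphi) <- frame$phi_names
  s_phi2 <- numeric(d); names(s_phi2) <- frame$phi_names
  s_res <- 0; s_rr <- 0
  s_pred <- numeric(frame$n_obs); s_r2 <- numeric(frame$n_obs)

  traj_names <- c(frame$phi_names,
                  unlist(lapply(frame$phi_names, function(p)
                    setdiff(names(frame$coef_init[[p]]), "(Intercept)"))),
                  paste0("omega_", frame$phi_names),
                  switch(frame$error_kind, constant = "a",
                         proportional = "b", combined = c("a", "b")))
  traj <- matrix(NA_real_, K1 + K2, length(traj_names),
                 dimnames = list(NULL, traj_names))

  snapshot <- function() {
    out <- numeric(0)
    for (p in frame$phi_names) out[p] <- exp(gamma[[p]][["(Intercept)"]])
    for (p in frame$phi_names) {
      b <- setdiff(names(gamma[[p]]), "(Intercept)")
      if (length(b)) out[b] <- gamma[[p]][b]
    }
    out[paste0("omega_", frame$phi_names)] <- omega
    out[switch(frame$error_kind, constant = "a", proportional = "b",
               combined = c("a", "b"))] <-
      switch(frame$error_kind, constant = err[["a"]],
             proportional = err[["b"]], combined = err[c("a", "b")])
    out
  }

  for (k in seq_len(K1 + K2)) {
    mu <- .frame_mu(frame, gamma)
    for (rep in seq_len(control$mh_reps)) {
      st <- .mh_sweep(frame, phi, ll_y, mu, omega, err, scales,
                      control$accept_target)
      phi <- st$phi; ll_y <- st$ll_y; scales <- st$scales
    }
    if (any(!is.finite(ll_y))) {
      stop_gabapk("non-finite likelihood at iteration ", k,
                  class = "gabapk_numeric_error")
    }
    step <- if (k == 1) 1 else if (k <= K1) 1 else 1 / (k - K1)

    preds <- .predict_phi(frame, phi)
    resid2 <- (frame$y - preds)^2
    for (p in frame$phi_names) {
      s_xphi[[p]] <- s_xphi[[p]] +
        step * (drop(crossprod(frame$X[[p]], phi[, p])) - s_xphi[[p]])
    }
    s_phi2 <- s_phi2 + step * (colSums(phi^2) - s_phi2)
    s_res <- s_res + step * (sum(resid2) - s_res)
    s_pred <- s_pred + step * (preds - s_pred)
    s_r2 <- s_r2 + step * (resid2 - s_r2)
    if (frame$error_kind == "proportional") {
      s_rr <- s_rr + step * (sum(resid2 / pmax(preds^2, 1e-12)) - s_rr)
    }

    # M-step
    for (p in frame$phi_names) {
      gamma[[p]] <- .mstep_coef(frame$XtX[[p]], s_xphi[[p]], gamma[[p]],
                                frame$coef_fixed[[p]])
    }
    mu <- .frame_mu(frame, gamma)
    for (j in seq_len(d)) {
      p <- frame$phi_names[j]
      if (!frame$omega_est[j]) next
      cp <- gamma[[p]]
      om2 <- (s_phi2[j] - 2 * sum(cp * s_xphi[[p]]) +
                drop(crossprod(cp, frame$XtX[[p]] %*% cp))) / n
      if (k <= K1 && control$anneal > 0) {
        om2 <- max(om2, control$anneal * omega[j]^2)
      }
      omega[j] <- sqrt(max(om2, control$omega_floor^2))
    }
    if (length(err_est)) {
      if (frame$error_kind == "constant") {
        a2 <- s_res / frame$n_obs
        if (k <= K1 && control$anneal > 0) {
          a2 <- max(a2, control$anneal * err[["a"]]^2)
        }
        err[["a"]] <- sqrt(max(a2, 1e-8))
      } else if (frame$error_kind == "proportional") {
        b2 <- s_rr / frame$n_obs
        if (k <= K1 && control$anneal > 0) {
          b2 <- max(b2, control$anneal * err[["b"]]^2)
        }
        err[["b"]] <- sqrt(max(b2, 1e-8))
      } else {
        nll <- function(lp) {
          v <- exp(2 * lp[1]) + exp(2 * lp[2]) * s_pred^2
          0.5 * sum(log(v) + s_r2 / v)
        }
        opt <- stats::optim(log(pmax(err[c("a", "b")], 1e-4)), nll,
                            method = "Nelder-Mead")
        err[c("a", "b")] <- exp(opt$par)
      }
    }
    traj[k, ] <- snapshot()
  }

  estimates <- snapshot()
  fit <- structure(
    list(estimates = estimates, gamma = gamma, omega = omega, err = err,
         frame = frame, trajectory = traj, phi = phi,
         control = control, seed = seed, dataset = dataset,
         model = model, n_params = .count_params(frame)),
    class = "saem_fit")
  fit$ebe <- .ebe_laplace(fit)
  fit$model_updated <- .writeback_model(fit)
  fit
}

# number of estimated parameters (for AIC/BIC)
.count_params <- function(frame) {
  p <- sum(vapply(frame$phi_names, function(pn)
    sum(!frame$coef_fixed[[pn]]), 0L))
  p <- p + sum(frame$omega_est)
  if (!frame$error_fixed) {
    p <- p + switch(frame$error_kind, constant = 1L, proportional = 1L,
                    combined = 2L)
  }
  p
}

# write estimates back into a pop_model (used for simulation & reporting)
.writeback_model <- function(fit) {
  m <- fit$model
  frame <- fit$frame
  for (p in names(m$init)) {
    if (p %in% frame$phi_names) {
      m$init[[p]] <- exp(fit$gamma[[p]][["(Intercept)"]])
    }
  }
  for (i in seq_along(m$covariate_effects)) {
    ce <- m$covariate_effects[[i]]
    bn <- .beta_name(ce)
    ce$beta <- fit$gamma[[ce$parameter]][[bn]]
    ce$ref <- frame$effects[[bn]]$ref
    m$covariate_effects[[i]] <- ce
  }
  for (p in names(m$omega)) m$omega[[p]] <- fit$omega[[p]]
  m$error$a <- unname(fit$err[["a"]])
  m$error$b <- unname(fit$err[["b"]])
  m
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("SAEM fit:", x$frame$n, "subjects,", x$frame$n_obs, "observations\n")
  cat("iterations:", nrow(x$trajectory), " seed:", x$seed, "\n")
  cat("estimates:\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Extract estimates from a SAEM fit
#' @param object a `saem_fit`
#' @param ... ignored
#' @export
coef.saem_fit <- function(object, ...) object$estimates

# Laplace machinery at the final estimates: per-subject posterior mode
# (the EBE) and covariance, used by the importance-sampling likelihood,
# residual diagnostics and shrinkage.
.ebe_laplace <- function(fit) {
  frame <- fit$frame
  mu <- .frame_mu(frame, fit$gamma)
  d <- frame$d
  mode <- matrix(NA_real_, frame$n, d,
                 dimnames = list(NULL, frame$phi_names))
  covs <- vector("list", frame$n)
  ok <- logical(frame$n)
  for (i in seq_len(frame$n)) {
    nlpost <- function(phii) {
      psi <- .phi_to_psi_one(frame, phii, i)
      pred <- .predict_one(frame, psi, i)
      sdv <- .err_sd(pred, fit$err, frame$error_kind)
      yi <- frame$y[frame$isubj_obs == i]
      -(sum(stats::dnorm(yi, pred, sdv, log = TRUE)) +
          sum(stats::dnorm(phii, mu[i, ], fit$omega, log = TRUE)))
    }
    opt <- tryCatch(stats::nlminb(fit$phi[i, ], nlpost),
                    error = function(e) NULL)
    if (is.null(opt)) { covs[[i]] <- diag(fit$omega^2, d); mode[i, ] <- fit$phi[i, ]; next }
    mode[i, ] <- opt$par
    H <- tryCatch(stats::optimHess(opt$par, nlpost), error = function(e) NULL)
    covi <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(covi) || any(!is.finite(covi)) ||
        any(diag(as.matrix(covi)) <= 0)) {
      covi <- diag(fit$omega^2, d)
    } else {
      covi <- as.matrix(covi)
      # symmetrise and ensure positive definiteness
      covi <- (covi + t(covi)) / 2
      ev <- eigen(covi, symmetric = TRUE)
      if (any(ev$values <= 0)) {
        covi <- ev$vectors %*% diag(pmax(ev$values, 1e-8), d) %*% t(ev$vectors)
      }
      ok[i] <- TRUE
    }
    covs[[i]] <- covi
  }
  list(mode = mode, eta = mode - mu, cov = covs, ok = ok, mu = mu)
}

# subject-restricted helpers for the EBE optimiser
.phi_to_psi_one <- function(frame, phii, i) {
  psi <- list()
  for (j in seq_along(frame$phi_names)) psi[[frame$phi_names[j]]] <- exp(phii[j])
  for (p in names(frame$const)) {
    if (!p %in% frame$phi_names) psi[[p]] <- frame$const[[p]]
  }
  psi
}

.predict_one <- function(frame, psi, i) {
  sel <- frame$trip$isubj == i
  tau <- frame$trip$tau[sel]; w <- frame$trip$w[sel]
  iobs <- frame$trip$iobs[sel]
  ke <- psi$Cl / psi$V
  val <- if (frame$structural == "first_order") {
    .fo_terms(tau, w, psi$V, psi$ka, ke)
  } else {
    .transit_terms(tau, w, psi$V, ke, psi$ktr, frame$n_transit)
  }
  as.vector(rowsum(val, iobs, reorder = TRUE))
}

#' Empirical Bayes estimates (posterior modes of the random effects)
#'
#' @param fit a `saem_fit`
#' @return matrix of per-subject eta estimates (subjects x random effects),
#'   with a `flag` attribute marking subjects whose Laplace covariance had
#'   to fall back to the population covariance
#' @export
empirical_bayes <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  eta <- fit$ebe$eta
  attr(eta, "flag") <- !fit$ebe$ok
  eta
}

#' Eta-shrinkage per random effect
#'
#' 100 (1 - SD(EBE)/omega): near 0 when individual data are rich, near
#' 100 when the prior dominates. Parameters whose omega was fixed at 0
#' (no between-subject variability) are reported as NA.
#'
#' @param fit a `saem_fit`
#' @return named numeric vector, percent
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  eta <- fit$ebe$eta
  declared <- unique(c(fit$frame$phi_names, names(fit$model$omega),
                       names(fit$model$omega_fixed)))
  out <- stats::setNames(rep(NA_real_, length(declared)), declared)
  for (p in fit$frame$phi_names) {
    om <- fit$omega[[p]]
    if (om > 0) out[p] <- 100 * (1 - stats::sd(eta[, p]) / om)
  }
  out
}

#' Multi-run convergence assessment
#'
#' Refits the model `n_runs` times with distinct seeds and initial values
#' perturbed by a log-uniform factor, and reports the per-parameter spread
#' of the final estimates. Parameters whose relative spread
#' (max - min)/|median| exceeds `threshold` percent are flagged as
#' unstable -- the practical criterion for deciding to fix a poorly
#' identified parameter (as done for the absorption rate constant).
#'
#' @param dataset a [pk_dataset()]
#' @param model a [pop_model()]
#' @param control a [saem_control()]
#' @param n_runs number of runs, >= 2
#' @param base_seed first seed; runs use `base_seed + 0:(n_runs-1)`
#' @param perturb half-width of the log-uniform initial perturbation
#' @param threshold flagging threshold, percent relative spread
#' @return list with `summary` (data.frame), `estimates` (runs x params),
#'   and `failures`
#' @export
convergence_assessment <- function(dataset, model, control = saem_control(),
                                   n_runs = 5, base_seed = 1,
                                   perturb = 0.3, threshold = 15) {
  stopifnot(n_runs >= 2)
  runs <- vector("list", n_runs)
  failures <- character(0)
  for (r in seq_len(n_runs)) {
    seed_r <- base_seed + r - 1
    m <- model
    set.seed(seed_r * 7919)
    m$init <- m$init * exp(stats::runif(length(m$init), -perturb, perturb))
    runs[[r]] <- tryCatch(
      coef(fit_saem(dataset, m, control, seed = seed_r)),
      error = function(e) {
        failures <<- c(failures, paste0("run ", r, ": ", conditionMessage(e)))
        NULL
      })
  }
  est <- do.call(rbind, runs[!vapply(runs, is.null, TRUE)])
  if (is.null(est) || nrow(est) < 2) {
    stop_gabapk("fewer than two successful runs", class = "gabapk_numeric_error")
  }
  med <- apply(est, 2, stats::median)
  spread <- 100 * (apply(est, 2, max) - apply(est, 2, min)) / pmax(abs(med), 1e-12)
  summary <- data.frame(parameter = colnames(est),
                        min = apply(est, 2, min), median = med,
                        max = apply(est, 2, max),
                        rel_spread_pct = spread,
                        flagged = spread > threshold,
                        row.names = NULL)
  list(summary = summary, estimates = est, failures = failures,
       threshold = threshold)
}
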
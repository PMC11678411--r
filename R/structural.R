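#' Saturable oral bioavailability
#'
#' Gabapentin is absorbed by a saturable L-amino-acid transporter, so the
#' absorbed fraction falls with the size of the dose:
#' \deqn{F(Dose) = Dmax / (D50 + Dose)}
#' with Dmax = 823 and D50 = 1120 fixed to previously published values.
#' The ratio is dimensionless with the dose in mg; it is strictly
#' decreasing in dose and bounded above by Dmax/D50 (about 0.735).
#'
#' @param dose dose amount, mg (>= 0, vectorised)
#' @param dmax saturation numerator, default 823
#' @param d50 dose at which absorption is 50\% saturated, default 1120
#' @return bioavailable fraction(s)
#' @examples
#' bioavailability(300)   # 823/1420
#' @export
bioavailability <- function(dose, dmax = 823, d50 = 1120) {
  if (any(dose < 0)) {
    stop_gabapk("dose must be non-negative", class = "gabapk_domain_error")
  }
  stopifnot(dmax > 0, d50 > 0)
  dmax / (d50 + dose)
}

#' Structural PK parameter set
#'
#' One-compartment disposition with oral absorption: volume `V` (L),
#' clearance `Cl` (L/h), absorption rate `ka` (1/h), optional lag `tlag`
#' (h) and optional transit-chain settings (`n_transit` serial compartments
#' at rate `ktr`). `ke = Cl/V` is derived. Bioavailability constants
#' `dmax`/`d50` ride along so a parameter set fully determines a
#' concentration profile.
#'
#' @param V volume of distribution, L
#' @param Cl clearance, L/h
#' @param ka absorption rate constant, 1/h
#' @param tlag absorption lag time, h
#' @param n_transit number of transit compartments (0 = plain first order)
#' @param ktr transit rate constant, 1/h (required when `n_transit` > 0)
#' @param dmax,d50 bioavailability constants, see [bioavailability()];
#'   `dmax = NULL` selects constant (dose-independent) bioavailability of 1
#' @export
structural_params <- function(V, Cl, ka = 0.778, tlag = 0,
                              n_transit = 0, ktr = NULL,
                              dmax = 823, d50 = 1120) {
  stopifnot(V > 0, Cl > 0, ka > 0, tlag >= 0, n_transit >= 0)
  if (n_transit > 0 && (is.null(ktr) || ktr <= 0)) {
    stop_gabapk("transit model needs ktr > 0", class = "gabapk_domain_error")
  }
  structure(list(V = V, Cl = Cl, ka = ka, tlag = tlag,
                 n_transit = as.integer(n_transit), ktr = ktr,
                 dmax = dmax, d50 = d50, ke = Cl / V),
            class = "structural_params")
}

.dose_f <- function(amount, dmax, d50) {
  if (is.null(dmax)) rep(1, length(amount)) else bioavailability(amount, dmax, d50)
}

# Core first-order evaluation on flat vectors: for each (time, dose) pair
# already expanded to tau = t - dose_time - tlag and w = F * amount, return
# the per-pair concentration contribution. ka, ke, V may be per-pair
# vectors. Uses the analytic ka -> ke limit when the rates nearly coincide.
.fo_terms <- function(tau, w, V, ka, ke) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tau <- tau[pos]; w <- w[pos]
  V <- rep_len(V, length(out))[pos]
  ka <- rep_len(ka, length(out))[pos]
  ke <- rep_len(ke, length(out))[pos]
  degenerate <- abs(ka - ke) / ka < 1e-8
  val <- numeric(length(tau))
  if (any(!degenerate)) {
    i <- !degenerate
    val[i] <- w[i] * ka[i] / (V[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * tau[i]) - exp(-ka[i] * tau[i]))
  }
  if (any(degenerate)) {
    i <- degenerate
    val[i] <- w[i] * ka[i] * tau[i] * exp(-ka[i] * tau[i]) / V[i]
  }
  out[pos] <- val
  out
}

#' Concentration under first-order absorption (closed form)
#'
#' Superposition over the dosing history of the classic one-compartment
#' oral solution, each dose scaled by its own saturable bioavailable
#' fraction:
#' \deqn{C(t) = \sum_d F(D_d) D_d k_a / (V (k_a - k_e))
#'   (e^{-k_e \tau_d} - e^{-k_a \tau_d})}
#' with \eqn{\tau_d = t - t_d - tlag} and terms dropped while
#' \eqn{\tau_d \le 0}. When \eqn{|k_a - k_e|/k_a < 10^{-8}} the analytic
#' limit \eqn{F D k_a \tau e^{-k_a \tau} / V} replaces the difference
#' quotient to avoid catastrophic cancellation. mg doses and L volumes
#' give mg/L = ug/mL directly.
#'
#' @param t evaluation time(s), hours since first dose
#' @param doses data.frame with columns `time`, `amount` (sorted by time)
#' @param params a [structural_params()] object
#' @return concentration(s), ug/mL
#' @export
conc_first_order <- function(t, doses, params) {
  stopifnot(inherits(params, "structural_params"))
  f <- .dose_f(doses$amount, params$dmax, params$d50)
  w <- f * doses$amount
  vapply(t, function(tt) {
    tau <- tt - doses$time - params$tlag
    sum(.fo_terms(tau, w, params$V, params$ka, params$ke))
  }, numeric(1))
}

#' Concentration under transit-compartment absorption
#'
#' The dose passes `n_transit` serial compartments and one absorption
#' compartment, all draining at rate `ktr`, before reaching the central
#' compartment (elimination `ke`). For an equal-rate chain the amount
#' reaching the central compartment has the closed form
#' \deqn{A_c(t) = F D (k_{tr}/(k_{tr}-k_e))^{n+1} e^{-k_e t}
#'   P(n + 1, (k_{tr}-k_e) t)}
#' where \eqn{P} is the regularised lower incomplete gamma function
#' (`pgamma`). When \eqn{k_{tr} \le k_e} (where that form is invalid) the
#' transit chain ODEs are integrated numerically with `deSolve`. With
#' `n_transit = 0` the model coincides with first-order absorption at rate
#' `ktr`.
#'
#' @inheritParams conc_first_order
#' @return concentration(s), ug/mL
#' @export
conc_transit <- function(t, doses, params) {
  stopifnot(inherits(params, "structural_params"), params$n_transit >= 0)
  if (is.null(params$ktr) || params$ktr <= 0) {
    stop_gabapk("transit model needs ktr > 0", class = "gabapk_domain_error")
  }
  n <- params$n_transit
  ktr <- params$ktr; ke <- params$ke; V <- params$V
  f <- .dose_f(doses$amount, params$dmax, params$d50)
  w <- f * doses$amount
  lam <- ktr - ke
  if (lam > 1e-10 * ktr) {
    vapply(t, function(tt) {
      tau <- tt - doses$time - params$tlag
      pos <- tau > 0
      if (!any(pos)) return(0)
      amt <- w[pos] * (ktr / lam)^(n + 1) * exp(-ke * tau[pos]) *
        stats::pgamma(lam * tau[pos], n + 1)
      sum(amt) / V
    }, numeric(1))
  } else {
    .conc_transit_ode(t, doses, params)
  }
}

# numeric transit-chain solution (also the independent oracle in tests)
.conc_transit_ode <- function(t, doses, params, rtol = 1e-10, atol = 1e-12) {
  n <- params$n_transit
  ktr <- params$ktr; ke <- params$ke; V <- params$V
  f <- .dose_f(doses$amount, params$dmax, params$d50)
  nstate <- n + 2  # n transit + absorption + central
  deriv <- function(t, y, parms) {
    d <- numeric(nstate)
    chain <- n + 1  # compartments draining at ktr
    d[1] <- -ktr * y[1]
    if (chain > 1) {
      for (j in 2:chain) d[j] <- ktr * y[j - 1] - ktr * y[j]
    }
    d[nstate] <- ktr * y[chain] - ke * y[nstate]
    list(d)
  }
  event_times <- doses$time + params$tlag
  times <- sort(unique(c(0, event_times, t[t >= 0])))
  ynames <- paste0("c", seq_len(nstate))
  y0 <- stats::setNames(numeric(nstate), ynames)
  ev <- data.frame(var = ynames[1], time = event_times,
                   value = f * doses$amount, method = "add")
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        events = list(data = ev))
  if (attr(sol, "istate")[1] < 0) {
    stop_gabapk("transit ODE solver failed to converge",
                class = "gabapk_numeric_error")
  }
  central <- sol[, nstate + 1]
  out <- numeric(length(t))
  idx <- match(t, sol[, 1])
  ok <- !is.na(idx)
  out[ok] <- central[idx[ok]] / V
  out
}

#' Steady-state concentration for a regular regimen
#'
#' Closed-form accumulation of `conc_first_order` for `amount` mg every
#' `interval` hours at steady state, evaluated `t_after_dose` hours after
#' a dose.
#'
#' @param t_after_dose time since the last dose, h (0 <= t < interval)
#' @param amount dose, mg
#' @param interval dosing interval, h
#' @param params a [structural_params()] object
#' @export
conc_steady_state <- function(t_after_dose, amount, interval, params) {
  f <- .dose_f(amount, params$dmax, params$d50)
  ka <- params$ka; ke <- params$ke
  acc_e <- 1 / (1 - exp(-ke * interval))
  acc_a <- 1 / (1 - exp(-ka * interval))
  tau <- t_after_dose - params$tlag
  ifelse(tau >= 0,
         f * amount * ka / (params$V * (ka - ke)) *
           (exp(-ke * tau) * acc_e - exp(-ka * tau) * acc_a),
         NA_real_)
}
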
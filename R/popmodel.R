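#' Residual error model
#'
#' @param kind `"constant"` (SD = a), `"proportional"` (SD = b f) or
#'   `"combined"` (SD = sqrt(a^2 + (b f)^2)), with standard-normal residual
#'   epsilon
#' @param a additive SD, ug/mL
#' @param b proportional coefficient, dimensionless
#' @export
error_model <- function(kind = c("constant", "proportional", "combined"),
                        a = 1, b = 0.2) {
  kind <- match.arg(kind)
  stopifnot(a >= 0, b >= 0)
  if (kind == "constant" && a == 0) {
    stop_gabapk("constant error model needs a > 0", class = "gabapk_domain_error")
  }
  if (kind == "proportional" && b == 0) {
    stop_gabapk("proportional error model needs b > 0",
                class = "gabapk_domain_error")
  }
  structure(list(kind = kind, a = a, b = b), class = "error_model")
}

#' Residual standard deviation at a model prediction
#'
#' @param prediction model prediction(s), ug/mL
#' @param error an [error_model()]
#' @return SD(s), ug/mL
#' @export
residual_sd <- function(prediction, error) {
  switch(error$kind,
         constant = rep_len(error$a, length(prediction)),
         proportional = error$b * prediction,
         combined = sqrt(error$a^2 + (error$b * prediction)^2))
}

#' Gaussian observation log-density
#'
#' Log of the normal density of an observed concentration around the model
#' prediction with SD given by the residual error model.
#'
#' @param y observed concentration(s), ug/mL
#' @param prediction model prediction(s)
#' @param error an [error_model()]
#' @export
obs_loglik <- function(y, prediction, error) {
  sd <- residual_sd(prediction, error)
  if (any(sd <= 0)) {
    stop_gabapk("residual SD must be positive", class = "gabapk_domain_error")
  }
  stats::dnorm(y, mean = prediction, sd = sd, log = TRUE)
}

#' Covariate effect on a structural parameter
#'
#' Continuous covariates enter the log-parameter linearly as
#' beta * log(cov / ref) (log-transformed and centred at a reference
#' value, by default the dataset arithmetic mean); categorical covariates
#' enter as beta * indicator with the largest class as reference.
#'
#' @param parameter target structural parameter (`"V"`, `"Cl"`, `"ka"`, ...)
#' @param covariate covariate column name (e.g. `"SCR"`, `"WT"`, `"DM"`)
#' @param beta initial/true exponent
#' @param ref centering reference for continuous covariates; `NULL` means
#'   use the dataset mean at fit time
#' @param type `"continuous"` or `"categorical"`
#' @export
cov_effect <- function(parameter, covariate, beta = 0, ref = NULL,
                       type = c("continuous", "categorical")) {
  type <- match.arg(type)
  if (type == "continuous" && !is.null(ref) && ref <= 0) {
    stop_gabapk("reference value must be positive", class = "gabapk_domain_error")
  }
  structure(list(parameter = parameter, covariate = covariate,
                 beta = beta, ref = ref, type = type),
            class = "cov_effect")
}

.pk_par_names <- c("V", "Cl", "ka", "tlag", "ktr")

#' Population PK model specification
#'
#' Fully describes the statistical model: typical values of the structural
#' parameters, which of them are estimated, log-normal between-subject
#' random effects (diagonal, on V and Cl in the final gabapentin model),
#' covariate effects, the residual error model, the structural model
#' (first-order or transit absorption) and the bioavailability mode.
#' Individual parameters follow
#' \deqn{\log\psi_i = \log\psi_{pop} + \sum \beta \log(cov_i/ref) + \eta_i,
#'   \quad \eta_i \sim N(0, \omega^2).}
#'
#' @param init named vector of typical values to be estimated, e.g.
#'   `c(V = 45.4, Cl = 6.31)` (previously reported gabapentin values are
#'   the conventional starting point)
#' @param fixed named vector of structural parameters held fixed, e.g.
#'   `c(ka = 0.778, tlag = 0)`
#' @param omega named vector of random-effect SDs (log scale) to estimate
#' @param omega_fixed named vector of random-effect SDs held fixed (used
#'   e.g. to give a small fixed variability to a parameter that only
#'   carries a covariate effect)
#' @param covariate_effects list of [cov_effect()]s
#' @param error an [error_model()]
#' @param structural `"first_order"` or `"transit"`
#' @param bioavailability `"saturable"` (F = Dmax/(D50+Dose)) or
#'   `"constant"` (F = 1, dose-proportional)
#' @param dmax,d50 saturation constants, mg
#' @param n_transit transit compartment count for the transit model
#' @param error_fixed logical, hold the error parameters fixed
#' @export
pop_model <- function(init = c(V = 45.4, Cl = 6.31),
                      fixed = c(ka = 0.778, tlag = 0),
                      omega = c(V = 0.5, Cl = 0.3),
                      omega_fixed = c(),
                      covariate_effects = list(),
                      error = error_model("constant", a = 1),
                      structural = c("first_order", "transit"),
                      bioavailability = c("saturable", "constant"),
                      dmax = 823, d50 = 1120, n_transit = 3,
                      error_fixed = FALSE) {
  structural <- match.arg(structural)
  bioavailability <- match.arg(bioavailability)
  stopifnot(all(names(init) %in% .pk_par_names),
            all(names(fixed) %in% .pk_par_names),
            all(names(omega) %in% .pk_par_names),
            all(names(omega_fixed) %in% .pk_par_names))
  if (any(names(init) %in% names(fixed))) {
    stop_gabapk("parameter cannot be both estimated and fixed: ",
                paste(intersect(names(init), names(fixed)), collapse = ", "),
                class = "gabapk_config_error")
  }
  if (inherits(covariate_effects, "cov_effect")) {
    covariate_effects <- list(covariate_effects)
  }
  for (ce in covariate_effects) {
    if (!ce$parameter %in% c(names(init), names(fixed))) {
      stop_gabapk("covariate effect targets unknown parameter ", ce$parameter,
                  class = "gabapk_config_error")
    }
  }
  structure(list(init = init, fixed = fixed,
                 omega = omega, omega_fixed = omega_fixed,
                 covariate_effects = covariate_effects,
                 error = error, structural = structural,
                 bioavailability = bioavailability,
                 dmax = dmax, d50 = d50, n_transit = n_transit,
                 error_fixed = error_fixed),
            class = "pop_model")
}

#' The published final gabapentin model
#'
#' One-compartment, first-order absorption (ka fixed at 0.778 1/h, no lag),
#' saturable bioavailability (Dmax 823, D50 1120), V 44.61 L, Cl 5.73 L/h,
#' serum creatinine as a power-law covariate on Cl (beta -0.89, centred at
#' SCr 1.3 mg/dL), log-normal random effects omega_V 0.77 and omega_Cl
#' 0.28, and a constant residual error of SD 2.03 ug/mL. This doubles as
#' the default generating truth of the synthetic cohort module.
#'
#' @return a [pop_model()]
#' @export
final_model <- function() {
  pop_model(init = c(V = 44.61, Cl = 5.73),
            fixed = c(ka = 0.778, tlag = 0),
            omega = c(V = 0.77, Cl = 0.28),
            covariate_effects = list(
              cov_effect("Cl", "SCR", beta = -0.89, ref = 1.3)),
            error = error_model("constant", a = 2.03))
}

#' @export
print.pop_model <- function(x, ...) {
  cat("pop_model:", x$structural, "absorption,", x$bioavailability,
      "bioavailability\n")
  cat("  estimated:", paste(sprintf("%s=%.4g", names(x$init), x$init),
                            collapse = ", "), "\n")
  if (length(x$fixed)) {
    cat("  fixed:    ", paste(sprintf("%s=%.4g", names(x$fixed), x$fixed),
                              collapse = ", "), "\n")
  }
  if (length(x$omega) || length(x$omega_fixed)) {
    om <- c(x$omega, x$omega_fixed)
    cat("  omega:    ", paste(sprintf("%s=%.4g", names(om), om),
                              collapse = ", "), "\n")
  }
  for (ce in x$covariate_effects) {
    cat(sprintf("  beta_%s_%s = %.4g (ref %s)\n", ce$parameter, ce$covariate,
                ce$beta, if (is.null(ce$ref)) "data mean" else ce$ref))
  }
  cat("  error:", x$error$kind,
      sprintf("(a=%.4g, b=%.4g)\n", x$error$a, x$error$b))
  invisible(x)
}

# all structural parameter values (typical), estimated or fixed
.pop_values <- function(model) {
  vals <- c(model$init, model$fixed)
  if (!"tlag" %in% names(vals)) vals["tlag"] <- 0
  vals
}

.beta_name <- function(ce) paste0("beta_", ce$parameter, "_", ce$covariate)

# covariate column on the model's scale: log(cov/ref) or 0/1 indicator
.cov_column <- function(ce, covtab) {
  v <- covtab[[ce$covariate]]
  if (is.null(v)) {
    stop_gabapk("covariate ", ce$covariate, " not present in the dataset",
                class = "gabapk_config_error")
  }
  if (ce$type == "categorical") {
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      ref_level <- names(which.max(table(v)))
      as.numeric(v != ref_level)
    } else {
      as.numeric(as.logical(v))
    }
  } else {
    if (any(v <= 0)) {
      stop_gabapk("continuous covariate ", ce$covariate,
                  " must be positive for log-transformation",
                  class = "gabapk_config_error")
    }
    ref <- ce$ref %||% mean(v)
    log(v / ref)
  }
}

#' Map population parameters, covariates and random effects to
#' individual structural parameters
#'
#' Applies the log-linear model
#' \eqn{\log\psi_i = \log\psi_{pop} + \sum\beta x_i + \eta_i} parameter by
#' parameter. Parameters without a random effect use eta = 0. `tlag` is
#' kept on its natural scale (it is only ever fixed).
#'
#' @param model a [pop_model()]
#' @param covariates one-row (or n-row) data.frame of covariate values
#' @param eta named list/matrix of random effects per parameter (log scale);
#'   missing entries are 0
#' @return data.frame of per-row structural parameter values
#' @export
individual_params <- function(model, covariates, eta = NULL) {
  vals <- .pop_values(model)
  n <- nrow(covariates) %||% 1
  if (n == 0) n <- 1
  out <- as.data.frame(lapply(vals, rep_len, n))
  for (p in setdiff(names(vals), "tlag")) {
    lp <- rep_len(log(vals[[p]]), n)
    for (ce in model$covariate_effects) {
      if (ce$parameter == p) lp <- lp + ce$beta * .cov_column(ce, covariates)
    }
    e <- if (!is.null(eta) && !is.null(eta[[p]])) rep_len(eta[[p]], n) else 0
    out[[p]] <- exp(lp + e)
  }
  out
}
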
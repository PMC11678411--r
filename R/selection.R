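.is_categorical_col <- function(v) {
  is.logical(v) || is.character(v) || is.factor(v)
}

#' Compare candidate structural models
#'
#' Fits each candidate model to the data and ranks them by BIC (OFV and
#' AIC are reported alongside, with the OFV difference to the best model).
#' Candidates that fail to fit are ranked last with the failure message.
#' The default candidate set mirrors the models considered for oral
#' gabapentin: first-order absorption with saturable or constant
#' bioavailability, first-order with a fixed 0.31 h lag, and a
#' transit-compartment chain.
#'
#' @param dataset a [pk_dataset()]
#' @param candidates named list of [pop_model()]s; `NULL` selects the
#'   default set
#' @param control a [saem_control()]
#' @param seed fitting seed (one per candidate, offset by position); the
#'   same OFV seed is shared across candidates
#' @param n_samples importance samples for the OFV
#' @return data.frame ranked by BIC
#' @export
compare_structural <- function(dataset, candidates = NULL,
                               control = saem_control(), seed = 1,
                               n_samples = 1000) {
  if (is.null(candidates)) candidates <- default_candidates()
  stopifnot(length(candidates) >= 1)
  rows <- list(); fits <- list()
  for (j in seq_along(candidates)) {
    nm <- names(candidates)[j]
    fit <- tryCatch(fit_saem(dataset, candidates[[j]], control,
                             seed = seed + j - 1),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[nm]] <- data.frame(model = nm, ofv = NA, aic = NA, bic = NA,
                               converged = FALSE,
                               note = conditionMessage(fit))
      next
    }
    lr <- loglik_is(fit, n_samples = n_samples, seed = seed + 1e6)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, ofv = lr$ofv, aic = lr$aic,
                             bic = lr$bic, converged = TRUE, note = "")
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(!tab$converged, tab$bic), ]
  tab$dofv_vs_best <- tab$ofv - tab$ofv[1]
  row.names(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Default structural candidate set
#'
#' @param init initial typical values shared by all candidates
#' @param error starting error model
#' @export
default_candidates <- function(init = c(V = 45.4, Cl = 6.31),
                               error = error_model("constant", a = 1)) {
  list(
    fo_saturable_F = pop_model(init = init, fixed = c(ka = 0.778, tlag = 0),
                               omega = c(V = 0.5, Cl = 0.3), error = error,
                               bioavailability = "saturable"),
    fo_constant_F = pop_model(init = init, fixed = c(ka = 0.778, tlag = 0),
                              omega = c(V = 0.5, Cl = 0.3), error = error,
                              bioavailability = "constant"),
    fo_lag_saturable_F = pop_model(init = init,
                                   fixed = c(ka = 0.778, tlag = 0.31),
                                   omega = c(V = 0.5, Cl = 0.3),
                                   error = error,
                                   bioavailability = "saturable"),
    transit_saturable_F = pop_model(init = c(init, ktr = 1),
                                    fixed = c(tlag = 0),
                                    omega = c(V = 0.5, Cl = 0.3, ktr = 0.3),
                                    error = error, structural = "transit",
                                    n_transit = 3,
                                    bioavailability = "saturable"))
}

# refit the base model with a small fixed random effect on `parameter`
# when it carries none, so EBE-based gates are computable
.base_with_eta <- function(base_fit, parameter, control) {
  if (parameter %in% base_fit$frame$phi_names) return(base_fit)
  m <- base_fit$model
  m$omega_fixed[parameter] <- 0.05
  fit_saem(base_fit$dataset, m, control, seed = base_fit$seed)
}

#' Test one covariate on one parameter
#'
#' Implements the three-gate acceptance rule for covariate inclusion: the
#' covariate is accepted iff (1) adding it lowers the OFV by at least 3.84
#' (the chi-square(1) 5\% quantile), (2) the Wald test of the fitted beta
#' is significant at p <= 0.01, and (3) the Pearson correlation test (or
#' one-way ANOVA for categorical covariates) between the base model's
#' empirical Bayes etas of the target parameter and the covariate is
#' significant at p <= 0.01. Base and augmented OFVs are computed with the
#' same seed (common random numbers) so Monte-Carlo noise stays well below
#' the 3.84 gate.
#'
#' @param dataset a [pk_dataset()]
#' @param base_fit the fitted base model (a `saem_fit`)
#' @param covariate covariate column name
#' @param parameter target structural parameter
#' @param control a [saem_control()]
#' @param n_samples importance samples for OFV and Wald SE
#' @param ofv_seed seed shared by the base and augmented OFV evaluations
#' @return a `cov_test` list: dofv, wald_p, corr_p, beta, accepted,
#'   augmented fit
#' @export
test_covariate <- function(dataset, base_fit, covariate, parameter,
                           control = saem_control(), n_samples = 500,
                           ofv_seed = base_fit$seed + 1e6) {
  covtab <- covariate_table(dataset)
  v <- covtab[[covariate]]
  if (is.null(v)) {
    stop_gabapk("covariate ", covariate, " absent from dataset",
                class = "gabapk_config_error")
  }
  if (anyNA(v)) {
    stop_gabapk("covariate ", covariate, " missing for some subjects",
                class = "gabapk_config_error")
  }
  type <- if (.is_categorical_col(v)) "categorical" else "continuous"
  base_fit <- .base_with_eta(base_fit, parameter, control)

  aug_model <- base_fit$model_updated
  aug_model$covariate_effects <- c(aug_model$covariate_effects,
                                   list(cov_effect(parameter, covariate,
                                                   beta = 0, type = type)))
  aug_fit <- tryCatch(fit_saem(dataset, aug_model, control,
                               seed = base_fit$seed + 1),
                      error = function(e) e)
  bn <- paste0("beta_", parameter, "_", covariate)
  if (inherits(aug_fit, "error")) {
    return(structure(list(covariate = covariate, parameter = parameter,
                          dofv = NA_real_, wald_p = NA_real_,
                          corr_p = NA_real_, beta = NA_real_,
                          accepted = FALSE,
                          note = paste("augmented fit failed:",
                                       conditionMessage(aug_fit))),
                     class = "cov_test"))
  }
  ofv_base <- loglik_is(base_fit, n_samples, seed = ofv_seed)$ofv
  ofv_aug <- loglik_is(aug_fit, n_samples, seed = ofv_seed)$ofv
  dofv <- ofv_base - ofv_aug

  se_tab <- standard_errors(aug_fit, n_samples = n_samples,
                            seed = ofv_seed + 1)
  row <- se_tab[se_tab$parameter == bn, ]
  beta <- if (nrow(row) == 1) row$estimate else NA_real_
  wald_p <- if (nrow(row) == 1 && is.finite(row$se) && row$se > 0) {
    2 * stats::pnorm(-abs(beta / row$se))
  } else NA_real_

  eta <- base_fit$ebe$eta[, parameter]
  corr_p <- .eta_cov_p(eta, v, type)

  accepted <- isTRUE(dofv >= 3.84) && isTRUE(wald_p <= 0.01) &&
    isTRUE(corr_p <= 0.01)
  structure(list(covariate = covariate, parameter = parameter, dofv = dofv,
                 wald_p = wald_p, corr_p = corr_p, beta = beta,
                 accepted = accepted, fit = aug_fit,
                 ofv_base = ofv_base, ofv_aug = ofv_aug, note = ""),
            class = "cov_test")
}

#' @export
print.cov_test <- function(x, ...) {
  cat(sprintf("%s on %s: dOFV %.2f, Wald p %.4g, corr p %.4g -> %s\n",
              x$covariate, x$parameter, x$dofv, x$wald_p, x$corr_p,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

# p-value of the eta ~ covariate association
.eta_cov_p <- function(eta, v, type) {
  if (length(unique(v)) < 2) return(1)  # degenerate: constant covariate
  if (type == "categorical") {
    f <- factor(v)
    if (nlevels(droplevels(f)) < 2) return(1)
    stats::anova(stats::aov(eta ~ f))[["Pr(>F)"]][1]
  } else {
    stats::cor.test(eta, log(v))$p.value
  }
}

#' Screen covariates against the random effects
#'
#' Pearson correlation test for continuous covariates (log scale), one-way
#' ANOVA for categorical ones, against each random effect's empirical
#' Bayes estimates. Constant covariates get p = 1 with a degeneracy note.
#'
#' @param fit a `saem_fit`
#' @param dataset the fitted dataset
#' @param covariates covariate column names; default: every covariate
#'   column not already in the model
#' @return data.frame covariate x random effect with p-values and flags at
#'   p <= 0.01
#' @export
correlation_screen <- function(fit, dataset, covariates = NULL) {
  covtab <- covariate_table(dataset)
  used <- vapply(fit$model$covariate_effects, function(ce) ce$covariate, "")
  if (is.null(covariates)) {
    covariates <- setdiff(names(covtab), c("ID", used))
  }
  rows <- list()
  for (cv in covariates) {
    v <- covtab[[cv]]
    type <- if (.is_categorical_col(v)) "categorical" else "continuous"
    degenerate <- length(unique(v)) < 2
    for (p in fit$frame$phi_names) {
      pv <- .eta_cov_p(fit$ebe$eta[, p], v, type)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, random_effect = p, type = type, p_value = pv,
        flagged = pv <= 0.01,
        note = if (degenerate) "constant covariate" else "")
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

.default_stages <- function() {
  list(
    list(label = "renal function on Cl", parameter = "Cl",
         covariates = c("SCR", "CRCL", "EGFR", "AKI")),
    list(label = "body size on V", parameter = "V",
         covariates = c("WT", "IBW", "ABW", "LBW", "BMI", "OBESE")),
    list(label = "diabetes on ka", parameter = "ka",
         covariates = c("DM", "FPG", "METCAT")),
    list(label = "diabetes on V", parameter = "V",
         covariates = c("DM", "FPG", "METCAT")))
}

#' Clinical-question-ordered forward addition and backward deletion
#'
#' Stage 1 tests the renal function indicators (SCr, CrCl, eGFR, AKI) on
#' clearance and keeps the single best accepted one (largest OFV drop;
#' ties broken towards the covariate needing fewest derived inputs, i.e.
#' the order given). Stage 2 tests the body-size metrics on V; stages 3-4
#' test the diabetes-related covariates on ka and V. Remaining covariates
#' are then screened against the random effects (p <= 0.01) and any hits
#' are tested. Finally each retained covariate is removed in turn and kept
#' only if its removal raises the OFV by at least 6.63 (chi-square(1) at
#' p = 0.01). Renal covariates are mutually exclusive on Cl (they are
#' algebraically collinear through SCr), as are body-size metrics on V:
#' each stage admits at most one winner per target parameter.
#'
#' @param dataset a [pk_dataset()] carrying the full covariate set
#' @param control a [saem_control()]
#' @param base_model starting model (no covariates); default: first-order
#'   saturable-F model with ka fixed at 0.778
#' @param stages list of stages, each `list(label, parameter, covariates)`
#' @param n_samples importance samples per OFV evaluation
#' @param seed seed for the base fit
#' @return list with `trace` (every tested model with its statistics and
#'   decision), `final_model`, `final_fit`
#' @export
covariate_search <- function(dataset, control = saem_control(),
                             base_model = NULL, stages = .default_stages(),
                             n_samples = 500, seed = 1) {
  if (is.null(base_model)) {
    base_model <- pop_model(init = c(V = 45.4, Cl = 6.31),
                            fixed = c(ka = 0.778, tlag = 0),
                            omega = c(V = 0.5, Cl = 0.3),
                            error = error_model("constant", a = 1))
  }
  covtab <- covariate_table(dataset)
  needed <- unique(unlist(lapply(stages, `[[`, "covariates")))
  missing <- setdiff(needed, names(covtab))
  if (length(missing)) {
    stop_gabapk("dataset lacks covariate(s): ",
                paste(missing, collapse = ", "),
                class = "gabapk_config_error")
  }
  current_fit <- fit_saem(dataset, base_model, control, seed = seed)
  trace <- list()
  push <- function(stage, tst) {
    trace[[length(trace) + 1L]] <<- data.frame(
      stage = stage, covariate = tst$covariate, parameter = tst$parameter,
      dofv = tst$dofv, wald_p = tst$wald_p, corr_p = tst$corr_p,
      beta = tst$beta %||% NA_real_,
      decision = if (isTRUE(tst$accepted)) "accepted" else "rejected",
      note = tst$note %||% "")
  }

  for (st in stages) {
    tests <- lapply(st$covariates, function(cv) {
      tst <- test_covariate(dataset, current_fit, cv, st$parameter,
                            control, n_samples)
      push(st$label, tst)
      tst
    })
    acc <- Filter(function(t) isTRUE(t$accepted), tests)
    if (length(acc)) {
      # largest dOFV wins; ties resolved by listed order (fewest derived
      # inputs first), which `which.max` provides
      best <- acc[[which.max(vapply(acc, `[[`, 0, "dofv"))]]
      current_fit <- best$fit
      trace[[length(trace) + 1L]] <- data.frame(
        stage = st$label, covariate = best$covariate,
        parameter = best$parameter, dofv = best$dofv,
        wald_p = best$wald_p, corr_p = best$corr_p, beta = best$beta,
        decision = "added", note = "stage winner")
    }
  }

  # residual screening of everything not yet in the model
  screen <- correlation_screen(current_fit, dataset)
  hits <- screen[screen$flagged, , drop = FALSE]
  for (r in seq_len(nrow(hits))) {
    tst <- test_covariate(dataset, current_fit, hits$covariate[r],
                          hits$random_effect[r], control, n_samples)
    push("random-effect screen", tst)
    if (isTRUE(tst$accepted)) current_fit <- tst$fit
  }

  # backward deletion
  kept <- current_fit$model$covariate_effects
  if (length(kept)) {
    full_ofv <- loglik_is(current_fit, n_samples,
                          seed = current_fit$seed + 1e6)$ofv
    for (i in rev(seq_along(current_fit$model$covariate_effects))) {
      ce <- current_fit$model_updated$covariate_effects[[i]]
      reduced <- current_fit$model_updated
      reduced$covariate_effects <- reduced$covariate_effects[-i]
      red_fit <- fit_saem(dataset, reduced, control,
                          seed = current_fit$seed)
      red_ofv <- loglik_is(red_fit, n_samples,
                           seed = current_fit$seed + 1e6)$ofv
      increase <- red_ofv - full_ofv
      keep <- increase >= 6.63
      trace[[length(trace) + 1L]] <- data.frame(
        stage = "backward deletion", covariate = ce$covariate,
        parameter = ce$parameter, dofv = increase, wald_p = NA_real_,
        corr_p = NA_real_, beta = ce$beta,
        decision = if (keep) "retained" else "removed",
        note = "dOFV is the increase on deletion")
      if (!keep) {
        current_fit <- red_fit
        full_ofv <- red_ofv
      }
    }
  }

  list(trace = do.call(rbind, trace),
       final_model = current_fit$model_updated,
       final_fit = current_fit)
}
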
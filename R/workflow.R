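#' One-command reproduction of the modelling workflow on synthetic data
#'
#' Runs the full model-building pipeline in the conventional order on a
#' synthetic TDM cohort: (1) generate the cohort and simulate
#' concentrations from the generating truth; (2) compare structural
#' models (first-order with saturable or constant bioavailability, fixed
#' lag, transit chain) by BIC; (3) compare constant / proportional /
#' combined residual error models by BIC on the winning structure; (4)
#' clinical-question-ordered covariate search with backward deletion; (5)
#' final fit with five-run convergence assessment; (6) nonparametric
#' bootstrap, VPC and residual diagnostics; (7) a recovery table of truth
#' versus estimate. Fully deterministic given `seed`.
#'
#' @param config a [cohort_config()]
#' @param truth generating [pop_model()]
#' @param seed master seed
#' @param control a [saem_control()] shared by all fits
#' @param n_boot bootstrap replicates
#' @param vpc_rep VPC simulation replicates
#' @param n_samples importance samples per OFV evaluation
#' @param recovery_tol named relative-error tolerances used to flag the
#'   recovery table (covariate betas are compared absolutely)
#' @param include_transit include the (slower) transit candidate in the
#'   structural comparison
#' @param out_dir if non-NULL, write `report.json` and the plotted
#'   quantities as CSVs there
#' @return a `gabapk_report` list
#' @export
run_workflow <- function(config = cohort_config(), truth = final_model(),
                         seed = 1, control = saem_control(),
                         n_boot = 100, vpc_rep = 200, n_samples = 500,
                         recovery_tol = c(default = 0.25),
                         include_transit = TRUE, out_dir = NULL) {
  dataset <- synthetic_dataset(config, truth, seed = seed)

  cand <- default_candidates()
  if (!include_transit) cand$transit_saturable_F <- NULL
  structural <- compare_structural(dataset, cand, control, seed = seed,
                                   n_samples = n_samples)
  # structural choice mirrors the reference analysis: the two
  # bioavailability modes have equal complexity, so the better OFV/BIC
  # wins outright; added absorption complexity (lag, transit chain) is
  # adopted only on a significant improvement (OFV drop >= 3.84) over
  # the simple first-order model
  ofv_of <- function(nm) {
    v <- structural$ofv[structural$model == nm]
    if (!length(v) || is.na(v)) Inf else v
  }
  best_name <- if (ofv_of("fo_saturable_F") <= ofv_of("fo_constant_F")) {
    "fo_saturable_F"
  } else "fo_constant_F"
  for (nm in intersect(c("fo_lag_saturable_F", "transit_saturable_F"),
                       structural$model)) {
    if (ofv_of(nm) < ofv_of(best_name) - 3.84) best_name <- nm
  }
  best_model <- cand[[best_name]]

  err_tab <- list()
  for (kind in c("constant", "proportional", "combined")) {
    m <- best_model
    m$error <- error_model(kind, a = 1, b = 0.2)
    fit <- tryCatch(fit_saem(dataset, m, control, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit)) next
    lr <- loglik_is(fit, n_samples, seed = seed + 1e6)
    err_tab[[kind]] <- data.frame(error_model = kind, ofv = lr$ofv,
                                  aic = lr$aic, bic = lr$bic)
  }
  err_tab <- do.call(rbind, err_tab)
  err_best <- err_tab$error_model[which.min(err_tab$bic)]
  base_model <- best_model
  base_model$error <- error_model(err_best, a = 1, b = 0.2)

  search <- covariate_search(dataset, control, base_model = base_model,
                             n_samples = n_samples, seed = seed)
  final_fit <- search$final_fit

  conv <- convergence_assessment(dataset, search$final_model, control,
                                 n_runs = 5, base_seed = seed)
  boot <- pk_bootstrap(dataset, search$final_model, n_rep = n_boot,
                       seed = seed, control = control)
  vpc_res <- vpc(final_fit, n_rep = max(100, vpc_rep), seed = seed + 3e6)
  resid <- pk_residuals(final_fit, seed = seed + 2e6)
  shrink <- eta_shrinkage(final_fit)

  recovery <- .recovery_table(truth, final_fit, recovery_tol)

  report <- structure(
    list(seed = seed, config = config,
         n_subjects = n_subjects(dataset), n_obs = n_observations(dataset),
         structural = structural, structural_choice = best_name,
         error_models = err_tab,
         selection_trace = search$trace,
         final_model = search$final_model,
         estimates = coef(final_fit), shrinkage = shrink,
         convergence = conv$summary, bootstrap = boot$summary,
         bootstrap_unstable = boot$unstable,
         vpc = vpc_res, residuals = resid, recovery = recovery,
         final_fit = final_fit, dataset = dataset),
    class = "gabapk_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

# truth-vs-estimate table; betas compared absolutely, others relatively
.recovery_table <- function(truth, fit, tol) {
  tr_frame <- .build_frame(fit$dataset, truth)
  truth_vec <- c()
  for (p in tr_frame$phi_names) {
    truth_vec[p] <- exp(tr_frame$coef_init[[p]][["(Intercept)"]])
    b <- setdiff(names(tr_frame$coef_init[[p]]), "(Intercept)")
    if (length(b)) truth_vec[b] <- tr_frame$coef_init[[p]][b]
    truth_vec[paste0("omega_", p)] <- tr_frame$omega_init[[p]]
  }
  truth_vec[switch(tr_frame$error_kind, constant = "a", proportional = "b",
                   combined = c("a", "b"))] <-
    switch(tr_frame$error_kind, constant = tr_frame$error_init[["a"]],
           proportional = tr_frame$error_init[["b"]],
           combined = tr_frame$error_init[c("a", "b")])
  est <- coef(fit)
  common <- intersect(names(truth_vec), names(est))
  err <- vapply(common, function(nm) {
    if (startsWith(nm, "beta_")) est[nm] - truth_vec[nm]
    else (est[nm] - truth_vec[nm]) / truth_vec[nm]
  }, numeric(1))
  tl <- vapply(common, function(nm) {
    if (nm %in% names(tol)) tol[[nm]]
    else if ("default" %in% names(tol)) tol[["default"]]
    else 0.25
  }, numeric(1))
  data.frame(parameter = common, truth = truth_vec[common],
             estimate = est[common], error = err,
             relative = !startsWith(common, "beta_"),
             tolerance = tl, flagged = abs(err) > tl, row.names = NULL)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$selection_trace,
                   file.path(out_dir, "selection_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(report$vpc$band, file.path(out_dir, "vpc_bands.csv"),
                   row.names = FALSE)
  utils::write.csv(report$residuals, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE)
  utils::write.csv(report$recovery, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  json <- list(seed = report$seed, n_subjects = report$n_subjects,
               n_obs = report$n_obs,
               structural = report$structural[, c("model", "ofv", "aic", "bic")],
               error_models = report$error_models,
               estimates = as.list(report$estimates),
               shrinkage = as.list(report$shrinkage),
               convergence = report$convergence,
               bootstrap = report$bootstrap,
               recovery = report$recovery)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.gabapk_report <- function(x, ...) {
  cat("gabapk workflow report (seed", x$seed, ")\n")
  cat(x$n_subjects, "subjects,", x$n_obs, "observations\n\n")
  cat("structural ranking (by BIC):\n")
  print(x$structural[, c("model", "ofv", "bic")])
  cat("\nerror model ranking:\n"); print(x$error_models)
  cat("\nselected covariates:\n")
  ces <- x$final_model$covariate_effects
  if (!length(ces)) cat("  (none)\n")
  for (ce in ces) {
    cat(sprintf("  %s on %s (beta %.3f)\n", ce$covariate, ce$parameter,
                ce$beta))
  }
  cat("\nfinal estimates:\n"); print(round(x$estimates, 4))
  cat("\nrecovery vs generating truth:\n"); print(x$recovery)
  invisible(x)
}
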
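#' Read and write a population model as a YAML configuration
#'
#' The file carries the blocks `structural` (model type, bioavailability
#' mode, saturation constants, transit settings), `fixed_effects`
#' (estimated initial values and fixed parameter values),
#' `covariate_effects`, `random_effects` (estimated and fixed omegas)
#' and `error_model`. `write_model_yaml` followed by `read_model_yaml`
#' reproduces the model exactly.
#'
#' @param model a [pop_model()]
#' @param path file path
#' @return `read_model_yaml` returns a [pop_model()];
#'   `write_model_yaml` returns the path invisibly
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "pop_model"))
  cfg <- list(
    structural = list(type = model$structural,
                      bioavailability = model$bioavailability,
                      dmax = model$dmax, d50 = model$d50,
                      n_transit = model$n_transit),
    fixed_effects = list(estimated = as.list(model$init),
                         fixed = as.list(model$fixed)),
    covariate_effects = lapply(model$covariate_effects, function(ce) {
      list(parameter = ce$parameter, covariate = ce$covariate,
           beta = ce$beta, ref = ce$ref, type = ce$type)
    }),
    random_effects = list(estimated = as.list(model$omega),
                          fixed = as.list(model$omega_fixed)),
    error_model = list(kind = model$error$kind, a = model$error$a,
                       b = model$error$b, fixed = model$error_fixed))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  pop_model(
    init = unlist(cfg$fixed_effects$estimated),
    fixed = unlist(cfg$fixed_effects$fixed) %||% c(),
    omega = unlist(cfg$random_effects$estimated) %||% c(),
    omega_fixed = unlist(cfg$random_effects$fixed) %||% c(),
    covariate_effects = lapply(cfg$covariate_effects, function(ce) {
      cov_effect(ce$parameter, ce$covariate, beta = ce$beta,
                 ref = ce$ref, type = ce$type)
    }),
    error = error_model(cfg$error_model$kind, a = cfg$error_model$a,
                        b = cfg$error_model$b),
    structural = cfg$structural$type,
    bioavailability = cfg$structural$bioavailability,
    dmax = cfg$structural$dmax, d50 = cfg$structural$d50,
    n_transit = cfg$structural$n_transit,
    error_fixed = isTRUE(cfg$error_model$fixed))
}
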
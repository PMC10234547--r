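#' Write a population model to a YAML configuration file
#'
#' Serialises typical values, IIV covariance, residual-error magnitudes,
#' allometric settings and covariate effects so that a model (initial
#' estimates or final published values) can be stored and reloaded.
#'
#' @param m a [population_model]
#' @param path output file
#' @return `path`, invisibly
#' @export
model_to_config <- function(m, path) {
  cfg <- list(
    theta = as.list(m$theta),
    omega = lapply(seq_len(7), function(i) as.numeric(m$omega[i, ])),
    omega_structure = m$omega_structure,
    sigma = as.list(m$sigma),
    allometric = if (is.null(m$allometric)) NULL else
      list(ref = m$allometric$ref,
           exponents = as.list(m$allometric$exponents)),
    covariate_effects = lapply(m$covariate_effects, function(e) {
      list(parameter = e$parameter, covariate = e$covariate, kind = e$kind,
           coefficient = e$coefficient, reference = e$reference)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a population model from a YAML configuration file
#'
#' @param path file written by [model_to_config] (or by hand in the same
#'   layout)
#' @return a [population_model]
#' @export
model_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  omega <- do.call(rbind, cfg$omega)
  dimnames(omega) <- list(pk_param_names(), pk_param_names())
  effects <- lapply(cfg$covariate_effects, function(e) {
    covariate_effect(e$parameter, e$covariate, e$kind, e$coefficient,
                     e$reference)
  })
  allo <- if (is.null(cfg$allometric)) NULL else
    list(ref = cfg$allometric$ref,
         exponents = unlist(cfg$allometric$exponents))
  population_model(
    theta = unlist(cfg$theta), omega = omega, sigma = unlist(cfg$sigma),
    allometric = allo, covariate_effects = effects,
    omega_structure = cfg$omega_structure
  )
}
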
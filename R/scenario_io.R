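# Scenario configs are fully expressible as YAML: everything in
# scenario_config() plus optional population-parameter overrides.

#' Read / write a scenario configuration as YAML
#'
#' The YAML may contain any [scenario_config()] argument; a `pop` block
#' with `model`, `theta`, `bsv` and `sigma_prop` overrides the reference
#' population, and `design_overrides` is passed to
#' [build_cohort_design()].
#'
#' @param path YAML file.
#' @return A `scenario_config`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$pop)) {
    raw$pop <- pop_params(raw$pop$model %||% raw$model,
                          theta = unlist(raw$pop$theta),
                          bsv = unlist(raw$pop$bsv %||% list()),
                          sigma_prop = raw$pop$sigma_prop %||% 0.15)
  }
  do.call(scenario_config, raw)
}

#' @rdname read_scenario
#' @param cfg a `scenario_config`.
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- list(model = cfg$model, duration = cfg$duration,
              dose_group = cfg$dose_group,
              n_replicates = cfg$n_replicates,
              master_seed = cfg$master_seed, methods = cfg$methods,
              measures = cfg$measures, lloq = cfg$lloq,
              threshold = cfg$threshold, truth = cfg$truth,
              cv_formula = cfg$cv_formula,
              init_perturb = cfg$init_perturb,
              horizon_days = cfg$horizon_days,
              pop = list(model = cfg$pop$model$model_id,
                         theta = as.list(cfg$pop$theta),
                         bsv = as.list(cfg$pop$bsv[cfg$pop$bsv > 0]),
                         sigma_prop = cfg$pop$sigma_prop))
  yaml::write_yaml(out, path)
  invisible(path)
}
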
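# Replicate-study orchestration and the bias/precision metrics: scaled
# relative mean error (SMRE) and the replicate coefficient of variation
# (CV), plus relative-error quantiles and convergence bookkeeping.

#' Scaled relative mean error
#'
#' `SMRE = 1/N * sum((estimated_i - true_i) / true_i) * 100`, the mean of
#' the per-replicate relative errors in percent. `true_value` may be a
#' single reference or one truth per estimate.
#'
#' @param estimates numeric vector of estimates.
#' @param true_value reference value(s), non-zero.
#' @return SMRE in percent.
#' @examples
#' smre(c(80, 120), 100)
#' @export
smre <- function(estimates, true_value) {
  if (length(estimates) < 1) abort("need at least one estimate")
  if (any(true_value == 0)) abort("undefined metric: true value is zero")
  mean((estimates - true_value) / true_value) * 100
}

#' Per-replicate relative error
#'
#' @inheritParams smre
#' @return `(estimate - true) / true * 100`.
#' @export
relative_error <- function(estimates, true_value) {
  if (any(true_value == 0)) abort("undefined metric: true value is zero")
  (estimates - true_value) / true_value * 100
}

#' Replicate coefficient of variation
#'
#' The default (`"replicate"`) formula is
#' `CV = 1/N * sqrt(sum(((x_i - mean) / mean)^2)) * 100`. Note the leading
#' `1/N` sits outside the square root, so this statistic shrinks roughly
#' like `1/sqrt(N)` as replicates accumulate (duplicating the sample does
#' not leave it unchanged); it measures the precision of the replicate
#' study as a whole. The conventional sample CV (`sd/mean * 100`) is
#' available as `formula = "sample"`.
#'
#' @param estimates numeric vector.
#' @param formula `"replicate"` (default) or `"sample"`.
#' @return CV in percent.
#' @examples
#' cv_precision(c(90, 110))
#' @export
cv_precision <- function(estimates, formula = c("replicate", "sample")) {
  formula <- match.arg(formula)
  if (length(estimates) < 1) abort("need at least one estimate")
  m <- mean(estimates)
  if (m == 0) abort("undefined metric: mean of estimates is zero")
  if (formula == "replicate") {
    sqrt(sum(((estimates - m) / m)^2)) / length(estimates) * 100
  } else {
    sd(estimates) / m * 100
  }
}

.study_methods <- c("model", "nca_composite_mean", "nca_composite_geomean",
                    "nca_serial_mean", "nca_serial_geomean")

#' Scenario configuration for a replicate study
#'
#' Bundles everything [run_study()] needs: the simulating model and
#' population, the cohort design, the reported dose group, replicate count
#' and master seed, the BQL limit and TAT threshold, the truth convention,
#' and the estimation arms to run.
#'
#' @param model model id (`"ONE_CMT"`, `"ONE_CMT_MM"`, `"TWO_CMT"`).
#' @param duration cohort duration preset.
#' @param dose_group reported dose group in mg/kg/day (default 30).
#' @param n_replicates number of simulation replicates (default 200).
#' @param master_seed master seed for the study.
#' @param methods estimation arms (subset of `"model"`,
#'   `"nca_composite_mean"`, `"nca_composite_geomean"`,
#'   `"nca_serial_mean"`, `"nca_serial_geomean"`).
#' @param measures exposure measures to evaluate (NCA arms are always
#'   restricted to `auc24`, `cmax24`, `tat24`).
#' @param lloq lower limit of quantification (mg/ml).
#' @param threshold TAT threshold (mg/ml).
#' @param truth truth convention, `"group_mean"` or `"population_typical"`.
#' @param truth_scope which animals define an NCA arm's truth under the
#'   `"group_mean"` convention: `"dose_group"` (all animals of the dose
#'   group; the shared estimand when comparing estimator classes) or
#'   `"sampled_group"` (only the animals the scheme actually sampled;
#'   isolates the sampling scheme's own contribution to error when
#'   comparing composite with serial designs). The model arm always
#'   targets the dose-group truth.
#' @param cv_formula CV convention for the comparison table.
#' @param init_perturb multiplicative perturbation of the (true) initial
#'   estimates handed to the fitter.
#' @param horizon_days dosing horizon for the cumulative measures.
#' @param design_overrides named list forwarded to [build_cohort_design()].
#' @param pop optional [pop_params()] (defaults to the reference set for
#'   `model`).
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(model = "ONE_CMT", duration = "3_MONTHS",
                            dose_group = 30, n_replicates = 200,
                            master_seed = 1234,
                            methods = .study_methods,
                            measures = .measure_names,
                            lloq = 0.001, threshold = 0.01,
                            truth = c("group_mean", "population_typical"),
                            truth_scope = c("dose_group", "sampled_group"),
                            cv_formula = c("replicate", "sample"),
                            init_perturb = 1.5, horizon_days = 180,
                            design_overrides = list(), pop = NULL) {
  truth <- match.arg(truth)
  truth_scope <- match.arg(truth_scope)
  cv_formula <- match.arg(cv_formula)
  methods <- match.arg(methods, .study_methods, several.ok = TRUE)
  measures <- match.arg(measures, .measure_names, several.ok = TRUE)
  if (length(methods) == 0) abort("empty method list")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  pop <- pop %||% default_pop_params(model)
  design <- do.call(build_cohort_design,
                    c(list(duration = duration), design_overrides))
  if (!dose_group %in% design$dose_groups || dose_group <= 0) {
    abort("dose_group must be one of the design's active dose groups")
  }
  structure(
    list(model = model, duration = duration, dose_group = dose_group,
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed), methods = methods,
         measures = measures, lloq = lloq, threshold = threshold,
         truth = truth, truth_scope = truth_scope,
         cv_formula = cv_formula,
         init_perturb = init_perturb, horizon_days = horizon_days,
         design = design, pop = pop,
         scenario_id = paste(model, duration, paste0(dose_group, "mgkg"),
                             sep = "_")),
    class = "scenario_config")
}

.nca_measures <- c("auc24", "cmax24", "tat24")

# one replicate: simulate, filter, run every estimation arm
run_replicate <- function(cfg, r) {
  seed_r <- replicate_seed(cfg$master_seed, r)
  ds <- simulate_trial(cfg$design, cfg$pop, seed = seed_r, replicate = r)
  dsf <- apply_bql_filter(ds, cfg$lloq)
  eval_day <- max(cfg$design$satellite_scheme$sampling_days)
  truth_cache <- list()
  truth_for <- function(scope) {
    if (is.null(truth_cache[[scope]])) {
      roles <- switch(scope, all = c("TOXICITY", "SATELLITE"),
                      tox = "TOXICITY", sat = "SATELLITE")
      tr <- true_exposure(ds, cfg$pop, cfg$dose_group, eval_day,
                          cfg$threshold, cfg$truth, cfg$measures,
                          roles = roles)
      truth_cache[[scope]] <<- unlist(tr[1, .measure_names])
    }
    truth_cache[[scope]]
  }
  rows <- list()
  add_rows <- function(method, measure, estimate, scope,
                       converged = NA, covariance_ok = NA) {
    truth_vec <- truth_for(scope)
    rows[[length(rows) + 1]] <<- tibble(
      replicate = r, method = method, measure = measure,
      estimate = estimate, truth = unname(truth_vec[measure]),
      converged = converged, covariance_ok = covariance_ok)
  }
  nca_meas <- intersect(cfg$measures, .nca_measures)
  comp_day <- max(cfg$design$toxicity_scheme$sampling_days)
  for (m in cfg$methods) {
    if (m == "model") next
    kind <- if (grepl("geomean", m)) "GEOMETRIC" else "ARITHMETIC"
    est <- if (grepl("composite", m)) {
      prof <- composite_mean_profile(dsf, cfg$dose_group, comp_day, kind)
      nca_exposure_from_profile(prof, cfg$threshold)
    } else {
      serial_nca_summary(dsf, cfg$dose_group, eval_day, kind,
                         cfg$threshold)
    }
    scope <- if (cfg$truth_scope == "sampled_group") {
      if (grepl("composite", m)) "tox" else "sat"
    } else "all"
    for (meas in nca_meas) {
      add_rows(m, meas, est$estimate[est$measure == meas], scope)
    }
  }
  fit_info <- NULL
  if ("model" %in% cfg$methods) {
    fit <- suppressWarnings(
      fit_population(estimator_view(dsf), cfg$pop,
                     perturb = cfg$init_perturb))
    for (meas in cfg$measures) {
      est <- if (fit$converged) {
        exposure_from_fit(fit, cfg$dose_group, eval_day, cfg$threshold,
                          cfg$horizon_days,
                          measures = meas)[[meas]]
      } else NA_real_
      add_rows("model", meas, est, "all", fit$converged,
               fit$covariance_ok)
    }
    omega_named <- if (length(fit$omega_sd)) {
      as.list(setNames(fit$omega_sd,
                       paste0("omega_", names(fit$omega_sd))))
    } else list()
    fit_info <- tibble(replicate = r, converged = fit$converged,
                       covariance_ok = fit$covariance_ok, ofv = fit$ofv,
                       !!!as.list(fit$theta), !!!omega_named,
                       sigma = fit$sigma)
  }
  out <- bind_rows(rows)
  attr(out, "fit_info") <- fit_info
  out
}

#' Run a replicate simulation-estimation study
#'
#' For each replicate: simulate the full virtual study, apply the BQL
#' filter, run the configured NCA arms (on the composite and serial data)
#' and the FOCE-I model arm (on the integrated dataset combining all dose
#' groups, roles and sampling days), derive the exposure measures, and
#' score each estimate against the replicate's truth. Aggregates SMRE, CV,
#' relative-error quantiles and convergence/covariance rates. Fully
#' reproducible from the master seed; per-replicate failures are recorded
#' and never abort the study.
#'
#' @param cfg a [scenario_config()].
#' @param progress print a dot per replicate.
#' @return A `tk_study` object: `comparison` (the aggregated table, also
#'   available via [tidy()]), `results` (per-replicate estimates), and
#'   `failures`.
#' @export
run_study <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  results <- list()
  failures <- list()
  fits <- list()
  for (r in seq_len(cfg$n_replicates)) {
    out <- tryCatch(run_replicate(cfg, r), error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1]] <-
        tibble(replicate = r, message = conditionMessage(out))
    } else {
      results[[length(results) + 1]] <- out
      if (!is.null(attr(out, "fit_info"))) {
        fits[[length(fits) + 1]] <- attr(out, "fit_info")
      }
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  results <- bind_rows(results)
  if (nrow(results) == 0) abort("all replicates failed")
  comparison <- summarise_comparison(results, cfg)
  structure(list(comparison = comparison, results = results,
                 fits = bind_rows(fits), failures = bind_rows(failures),
                 config = cfg),
            class = "tk_study")
}

# aggregate per-replicate results into the comparison table
summarise_comparison <- function(results, cfg) {
  results |>
    mutate(rel_err = ifelse(.data$truth == 0, NA_real_,
                            (.data$estimate - .data$truth) /
                              .data$truth * 100),
           used = !is.na(.data$estimate) &
             (is.na(.data$converged) | .data$converged)) |>
    group_by(.data$method, .data$measure) |>
    summarise(
      n_replicates = dplyr::n(),
      n_used = sum(.data$used),
      smre = mean(.data$rel_err[.data$used]),
      cv = cv_precision(.data$estimate[.data$used], cfg$cv_formula),
      q05 = quantile(.data$rel_err[.data$used], 0.05, names = FALSE),
      q25 = quantile(.data$rel_err[.data$used], 0.25, names = FALSE),
      q50 = quantile(.data$rel_err[.data$used], 0.50, names = FALSE),
      q75 = quantile(.data$rel_err[.data$used], 0.75, names = FALSE),
      q95 = quantile(.data$rel_err[.data$used], 0.95, names = FALSE),
      convergence_rate = if (all(is.na(.data$converged))) NA_real_ else
        mean(.data$converged, na.rm = TRUE) * 100,
      covariance_rate = if (all(is.na(.data$covariance_ok))) NA_real_ else
        mean(.data$covariance_ok, na.rm = TRUE) * 100,
      .groups = "drop") |>
    mutate(scenario = cfg$scenario_id, cv_formula = cfg$cv_formula) |>
    select("scenario", dplyr::everything())
}

#' @export
print.tk_study <- function(x, ...) {
  cat("<tk_study>", x$config$scenario_id, "-",
      x$config$n_replicates, "replicates\n")
  if (nrow(x$failures) > 0) {
    cat("  failed replicates:", nrow(x$failures), "\n")
  }
  print(x$comparison, n = Inf)
  invisible(x)
}

#' Tidy / summarise a replicate study
#'
#' `tidy()` returns the comparison table (one row per method and measure:
#' SMRE, CV, relative-error quantiles, convergence rates); `glance()`
#' returns a one-row study summary.
#'
#' @param x a `tk_study`.
#' @param ... unused.
#' @export
tidy.tk_study <- function(x, ...) x$comparison

#' @rdname tidy.tk_study
#' @export
glance.tk_study <- function(x, ...) {
  model_rows <- x$results[x$results$method == "model", ]
  tibble(scenario = x$config$scenario_id,
         n_replicates = x$config$n_replicates,
         n_failed = nrow(x$failures),
         convergence_rate = if (nrow(model_rows)) {
           mean(model_rows$converged[!duplicated(model_rows$replicate)]) *
             100
         } else NA_real_,
         covariance_rate = if (nrow(model_rows)) {
           mean(model_rows$covariance_ok[
             !duplicated(model_rows$replicate)]) * 100
         } else NA_real_)
}

#' Write study tables to disk
#'
#' Writes the comparison table and the per-replicate results as tidy CSV,
#' plus a human-readable text rendering of the comparison table.
#'
#' @param study a `tk_study`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  stopifnot(inherits(study, "tk_study"))
  if (nrow(study$comparison) == 0) abort("empty comparison table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    comparison = file.path(dir, paste0(study$config$scenario_id,
                                       "_comparison.csv")),
    replicates = file.path(dir, paste0(study$config$scenario_id,
                                       "_replicates.csv")),
    text = file.path(dir, paste0(study$config$scenario_id,
                                 "_comparison.txt")))
  readr::write_csv(study$comparison, files[["comparison"]])
  readr::write_csv(study$results, files[["replicates"]])
  writeLines(c(paste("Scenario:", study$config$scenario_id),
               utils::capture.output(as.data.frame(study$comparison))),
             files[["text"]])
  invisible(files)
}
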
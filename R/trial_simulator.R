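# Realise a full virtual toxicology study into a long-format dataset of
# dose and observation records, with truth columns kept alongside for the
# evaluator (and stripped before anything reaches an estimator).

#' Simulate a complete virtual toxicology study
#'
#' Every animal in every dose group (toxicity and satellite roles) receives
#' its own individual parameters; all scheduled samples are realised with
#' proportional residual error. Satellite animals give full serial profiles
#' on the serial sampling days; toxicity animals are sampled at the
#' composite slots allocated (randomly, per sampling day) by
#' [allocate_composite_samples()]. The vehicle group is simulated (all-zero
#' concentrations) but carries no information and is excluded from
#' estimation downstream.
#'
#' All randomness for the replicate is drawn from a single stream seeded by
#' `seed`, so two calls with the same seed are identical.
#'
#' @param design a [build_cohort_design()] object.
#' @param pop a [pop_params()] object (model + typical values + BSV +
#'   residual SD).
#' @param seed integer seed for this replicate.
#' @param replicate optional replicate index stored in the provenance.
#' @return A `tk_dataset`: a tibble with columns `animal_id`, `cohort`,
#'   `dose_group` (mg/kg/day), `role` (`"TOXICITY"`/`"SATELLITE"`), `time`
#'   (h since first dose), `evid` (1 = dose, 0 = observation), `amt`
#'   (mg/kg, dose records), `dv` (observed mg/ml), `dv_true` (noise-free
#'   mg/ml), `mdv`. The realised individual parameters are attached as the
#'   `"animals"` attribute and provenance as `"provenance"`.
#' @export
simulate_trial <- function(design, pop, seed = NULL, replicate = NA_integer_) {
  stopifnot(inherits(design, "cohort_design"), inherits(pop, "pop_params"))
  model <- pop$model
  with_seed_if(seed, {
    records <- list()
    animal_tabs <- list()
    n_per_group <- design$toxicity_n + design$satellite_n
    dose_times <- (seq_len(design$duration_days) - 1) * 24
    for (g in seq_along(design$dose_groups)) {
      dose <- design$dose_groups[[g]]
      regimen <- dose_regimen(dose, interval = 24,
                              n_doses = design$duration_days)
      params <- sample_individual_params(pop, n_per_group)
      roles <- rep(c("TOXICITY", "SATELLITE"),
                   c(design$toxicity_n, design$satellite_n))
      ids <- sprintf("D%03d_%s%02d", dose,
                     ifelse(roles == "TOXICITY", "T", "S"),
                     c(seq_len(design$toxicity_n),
                       seq_len(design$satellite_n)))
      params$animal_id <- ids
      params$role <- roles
      params$dose_group <- dose
      animal_tabs[[g]] <- params

      # scheduled observation times per animal
      sched <- list()
      sat <- design$satellite_scheme
      for (day in sat$sampling_days) {
        for (id in ids[roles == "SATELLITE"]) {
          sched[[length(sched) + 1]] <-
            tibble(animal_id = id,
                   time = (day - 1) * 24 + sat$times_within_day)
        }
      }
      tox <- design$toxicity_scheme
      tox_ids <- ids[roles == "TOXICITY"]
      for (day in tox$sampling_days) {
        alloc <- allocate_composite_samples(
          length(tox_ids), tox$times_within_day,
          tox$replicates_per_timepoint)
        sched[[length(sched) + 1]] <-
          tibble(animal_id = tox_ids[alloc$animal_id],
                 time = (day - 1) * 24 + alloc$time)
      }
      obs <- bind_rows(sched) |> arrange(.data$animal_id, .data$time)

      group_records <- lapply(ids, function(id) {
        p <- params[params$animal_id == id, model$param_names]
        a_obs <- obs[obs$animal_id == id, ]
        true_c <- predict_conc(model, unlist(p), regimen, a_obs$time)
        obs_c <- simulate_observations(true_c, pop$sigma_prop)
        bind_rows(
          tibble(animal_id = id, time = dose_times, evid = 1L,
                 amt = dose, dv = NA_real_, dv_true = NA_real_, mdv = 1L),
          tibble(animal_id = id, time = a_obs$time, evid = 0L,
                 amt = NA_real_, dv = obs_c, dv_true = true_c, mdv = 0L)
        )
      })
      records[[g]] <- bind_rows(group_records) |>
        mutate(dose_group = dose,
               role = ifelse(grepl("_T", .data$animal_id), "TOXICITY",
                             "SATELLITE"))
    }
    ds <- bind_rows(records) |>
      mutate(cohort = design$duration) |>
      select("animal_id", "cohort", "dose_group", "role", "time", "evid",
             "amt", "dv", "dv_true", "mdv") |>
      arrange(.data$dose_group, .data$animal_id, .data$time, -.data$evid)
    attr(ds, "animals") <- bind_rows(animal_tabs)
    attr(ds, "provenance") <- list(model_id = model$model_id,
                                   duration = design$duration,
                                   seed = seed, replicate = replicate,
                                   sigma_prop = pop$sigma_prop,
                                   n_doses = design$duration_days)
    class(ds) <- c("tk_dataset", class(ds))
    ds
  })
}

#' Remove observations below the lower limit of quantification
#'
#' Observation records with `dv < lloq` are dropped (mimicking analyses in
#' which below-quantification data are omitted rather than imputed); dose
#' records are untouched. The number of removed records is reported and
#' stored in the `"n_bql_removed"` attribute.
#'
#' @param ds a `tk_dataset`.
#' @param lloq lower limit of quantification (mg/ml, >= 0; default 0.001
#'   i.e. 1 ug/ml).
#' @param quiet suppress the message.
#' @return The filtered `tk_dataset`.
#' @export
apply_bql_filter <- function(ds, lloq = 0.001, quiet = TRUE) {
  if (lloq < 0) abort("lloq must be >= 0")
  drop <- ds$evid == 0L & ds$dv < lloq
  out <- ds[!drop, ]
  n_removed <- sum(drop)
  if (!quiet) {
    inform(paste0("apply_bql_filter: removed ", n_removed,
                  " observation(s) below ", lloq, " mg/ml"))
  }
  attr(out, "animals") <- attr(ds, "animals")
  attr(out, "provenance") <- attr(ds, "provenance")
  attr(out, "n_bql_removed") <- n_removed
  class(out) <- class(ds)
  out
}

#' Estimator-facing view of a simulated dataset
#'
#' Strips the truth column and the individual-parameter attribute so that
#' estimation code can never see them.
#'
#' @param ds a `tk_dataset`.
#' @return A plain tibble with columns `animal_id`, `cohort`, `dose_group`,
#'   `role`, `time`, `evid`, `amt`, `dv`, `mdv`.
#' @export
estimator_view <- function(ds) {
  out <- as_tibble(ds[, c("animal_id", "cohort", "dose_group", "role",
                          "time", "evid", "amt", "dv", "mdv")])
  attr(out, "animals") <- NULL
  attr(out, "provenance") <- NULL
  out
}

#' Write / read a dataset in the long-format CSV dialect
#'
#' Columns `ID, TIME, AMT, DV, EVID, MDV, DOSEGRP, COHORT, ROLE` (the
#' truth column, when kept, goes into `TRUE_DV`). `read_tk_csv()` followed
#' by `write_tk_csv()` reproduces the file byte for byte.
#'
#' @param ds a `tk_dataset` or compatible tibble.
#' @param path output file.
#' @param keep_truth also write the `TRUE_DV` column (truth sidecar).
#' @return `path`, invisibly.
#' @export
write_tk_csv <- function(ds, path, keep_truth = FALSE) {
  # 15 significant digits: below the 17 needed to distinguish doubles, so
  # the text representation survives a read/write cycle byte for byte
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
  out <- tibble(ID = ds$animal_id, TIME = fmt(ds$time), AMT = fmt(ds$amt),
                DV = fmt(ds$dv), EVID = ds$evid, MDV = ds$mdv,
                DOSEGRP = fmt(ds$dose_group), COHORT = ds$cohort,
                ROLE = ds$role)
  if (keep_truth) out$TRUE_DV <- fmt(ds$dv_true)
  readr::write_csv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_tk_csv
#' @export
read_tk_csv <- function(path) {
  raw <- readr::read_csv(path, na = ".", show_col_types = FALSE)
  ds <- tibble(animal_id = as.character(raw$ID), cohort = raw$COHORT,
               dose_group = raw$DOSEGRP, role = raw$ROLE, time = raw$TIME,
               evid = as.integer(raw$EVID), amt = raw$AMT, dv = raw$DV,
               dv_true = if ("TRUE_DV" %in% names(raw)) raw$TRUE_DV else
                 NA_real_,
               mdv = as.integer(raw$MDV))
  class(ds) <- c("tk_dataset", class(ds))
  ds
}
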
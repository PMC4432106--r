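# Toxicology study designs: cohorts, dose groups, sampling schemes, and the
# random allocation of composite sampling slots to animals.
#
# Calendar mapping: "1 month" = 28 days, "week 4" = day 28, "week 13" =
# day 91, "3 months" = 91 days, "6 months" = 180 days. These are multiples
# of the 24-h dosing interval, so steady-state days line up with doses.

.tk_times <- c(0.1, 0.4, 1, 1.5, 4, 8, 24)

#' Within-day sampling scheme
#'
#' @param scheme `"COMPOSITE"` (each scheduled time point is covered by
#'   `replicates_per_timepoint` animals, each animal contributing only a
#'   subset of the time points) or `"SERIAL"` (every animal is sampled at
#'   every time point).
#' @param times_within_day sampling times in hours after that day's dose,
#'   strictly increasing, within \[0, 24\]. Default: 0.1, 0.4, 1, 1.5, 4, 8,
#'   24 h.
#' @param sampling_days study days (1-based) on which sampling occurs.
#' @param replicates_per_timepoint animals per time point (composite only,
#'   default 3).
#' @return A `sampling_scheme` object.
#' @export
sampling_scheme <- function(scheme = c("COMPOSITE", "SERIAL"),
                            times_within_day = .tk_times,
                            sampling_days = 1,
                            replicates_per_timepoint = 3) {
  scheme <- match.arg(scheme)
  if (is.unsorted(times_within_day, strictly = TRUE) ||
      any(times_within_day < 0) || any(times_within_day > 24)) {
    abort("times_within_day must be strictly increasing within [0, 24]")
  }
  if (any(sampling_days < 1)) abort("sampling_days must be >= 1")
  if (replicates_per_timepoint < 1) {
    abort("replicates_per_timepoint must be >= 1")
  }
  structure(list(scheme = scheme,
                 times_within_day = as.numeric(times_within_day),
                 sampling_days = as.integer(sampling_days),
                 replicates_per_timepoint =
                   as.integer(replicates_per_timepoint)),
            class = "sampling_scheme")
}

.cohort_presets <- list(
  `1_WEEK` = list(duration_days = 7L, toxicity_n = 4L, satellite_n = 3L,
                  serial_days = 1L, composite_days = 1L),
  `1_MONTH` = list(duration_days = 28L, toxicity_n = 10L, satellite_n = 3L,
                   serial_days = c(1L, 28L), composite_days = c(1L, 28L)),
  `3_MONTHS` = list(duration_days = 91L, toxicity_n = 12L, satellite_n = 3L,
                    serial_days = c(1L, 28L, 91L),
                    composite_days = c(28L, 91L))
)

#' Build a toxicology cohort design
#'
#' Standard chronic-toxicity protocol presets. All cohorts dose vehicle, 10,
#' 30 and 100 mg/kg/day orally once daily. The satellite group (3 animals
#' per dose group) provides full serial profiles on the cohort's sampling
#' days; the toxicity group provides composite samples, three animals per
#' time point, allocated at random under the constraint that all animals are
#' sampled an (as nearly as possible) equal number of times:
#'
#' * `1_WEEK`: toxicity n = 4, serial and composite sampling on day 1;
#' * `1_MONTH`: toxicity n = 10, sampling on days 1 and 28;
#' * `3_MONTHS`: toxicity n = 12, serial sampling on days 1, 28 and 91
#'   (week 4, week 13), composite sampling on days 28 and 91.
#'
#' The protocol tables leave the composite sampling days of the two shorter
#' cohorts implicit; this package sets them equal to the cohort's serial
#' sampling days.
#'
#' @param duration `"1_WEEK"`, `"1_MONTH"` or `"3_MONTHS"`.
#' @param ... named overrides among `dose_groups`, `toxicity_n`,
#'   `satellite_n`, `times_within_day`, `serial_days`, `composite_days`,
#'   `replicates_per_timepoint`, `duration_days`. Invariants are re-checked
#'   after overriding.
#' @return A `cohort_design` object.
#' @examples
#' build_cohort_design("3_MONTHS")
#' build_cohort_design("1_WEEK", toxicity_n = 8)
#' @export
build_cohort_design <- function(duration = c("1_WEEK", "1_MONTH",
                                             "3_MONTHS"), ...) {
  duration <- match.arg(duration)
  preset <- .cohort_presets[[duration]]
  over <- list(...)
  allowed <- c("dose_groups", "toxicity_n", "satellite_n",
               "times_within_day", "serial_days", "composite_days",
               "replicates_per_timepoint", "duration_days")
  if (length(over) && (is.null(names(over)) ||
                       !all(names(over) %in% allowed))) {
    abort(paste0("unknown design override; allowed: ",
                 paste(allowed, collapse = ", ")))
  }
  get_over <- function(name, default) over[[name]] %||% default
  duration_days <- get_over("duration_days", preset$duration_days)
  dose_groups <- get_over("dose_groups", c(0, 10, 30, 100))
  toxicity_n <- get_over("toxicity_n", preset$toxicity_n)
  satellite_n <- get_over("satellite_n", preset$satellite_n)
  times <- get_over("times_within_day", .tk_times)
  serial_days <- get_over("serial_days", preset$serial_days)
  composite_days <- get_over("composite_days", preset$composite_days)
  reps <- get_over("replicates_per_timepoint", 3L)
  if (toxicity_n < 1 || satellite_n < 1) abort("group sizes must be >= 1")
  if (any(dose_groups < 0)) abort("dose groups must be >= 0 mg/kg/day")
  if (any(serial_days > duration_days) ||
      any(composite_days > duration_days)) {
    abort("sampling days must lie within the study duration")
  }
  design <- structure(
    list(duration = duration,
         duration_days = as.integer(duration_days),
         dose_groups = as.numeric(dose_groups),
         toxicity_n = as.integer(toxicity_n),
         satellite_n = as.integer(satellite_n),
         toxicity_scheme = sampling_scheme("COMPOSITE", times,
                                           composite_days, reps),
         satellite_scheme = sampling_scheme("SERIAL", times, serial_days)),
    class = "cohort_design")
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", x$duration, "(", x$duration_days, "days )\n")
  cat("  dose groups (mg/kg/day):", paste(x$dose_groups, collapse = ", "),
      "\n")
  cat("  toxicity group: n =", x$toxicity_n, "per dose group, composite on",
      "day(s)", paste(x$toxicity_scheme$sampling_days, collapse = ", "),
      "\n")
  cat("  satellite group: n =", x$satellite_n,
      "per dose group, serial profiles on day(s)",
      paste(x$satellite_scheme$sampling_days, collapse = ", "), "\n")
  cat("  sampling times (h post dose):",
      paste(x$satellite_scheme$times_within_day, collapse = ", "), "\n")
  invisible(x)
}

#' Randomly allocate composite sampling slots to animals
#'
#' Each scheduled time point must be covered by exactly
#' `replicates_per_timepoint` distinct animals, and per-animal sample counts
#' may differ by at most one across the group. The allocation is drawn by
#' dealing randomly permuted animal sequences into time-point slots (which
#' enforces the equal-count constraint by construction) and redrawing when a
#' time point receives a duplicate animal.
#'
#' @param n_animals animals available.
#' @param times sampling times (identifies the time points).
#' @param replicates_per_timepoint animals per time point.
#' @param seed optional integer seed.
#' @return A tibble with columns `time` and `animal_id` (one row per slot).
#' @examples
#' allocate_composite_samples(8, c(0.1, 0.4, 1, 1.5, 4, 8, 24), 3, seed = 1)
#' @export
allocate_composite_samples <- function(n_animals, times,
                                       replicates_per_timepoint = 3,
                                       seed = NULL) {
  n_animals <- as.integer(n_animals)
  reps <- as.integer(replicates_per_timepoint)
  if (n_animals < 1) abort("n_animals must be >= 1")
  if (reps > n_animals) {
    abort(paste0("infeasible design: ", reps, " distinct animals per time ",
                 "point requested but only ", n_animals, " available"))
  }
  n_times <- length(times)
  n_slots <- n_times * reps
  draw <- function() {
    for (attempt in seq_len(2000)) {
      seq_animals <- unlist(lapply(seq_len(ceiling(n_slots / n_animals)),
                                   function(i) sample.int(n_animals)))
      slots <- seq_animals[seq_len(n_slots)]
      time_order <- sample.int(n_times)
      assign_time <- rep(time_order, each = reps)
      ok <- all(tapply(slots, assign_time,
                       function(a) length(unique(a)) == reps))
      if (ok) {
        return(tibble(time = times[assign_time], animal_id = slots) |>
                 arrange(.data$time, .data$animal_id))
      }
    }
    abort("could not find a valid composite allocation in 2000 attempts")
  }
  with_seed_if(seed, draw())
}
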
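# Independent numerical oracles (deSolve) and small dataset builders used
# across the test files. The oracles never share code with the package's
# own prediction paths.

# one-compartment first-order absorption/elimination, repeat oral bolus
ode_onecmt_oracle <- function(params, dose, n_doses, times, interval = 24) {
  p <- unlist(params)
  rhs <- function(t, y, parms) {
    list(c(-p[["KA"]] * y[1], p[["KA"]] * y[1] - p[["CL"]] / p[["V"]] * y[2]))
  }
  ev <- data.frame(var = "depot",
                   time = (seq_len(n_doses) - 1) * interval,
                   value = dose, method = "add")
  tt <- sort(unique(c(0, times, ev$time)))
  out <- deSolve::lsoda(c(depot = 0, central = 0), tt, rhs, NULL,
                        events = list(data = ev),
                        rtol = 1e-10, atol = 1e-12)
  out[match(times, out[, "time"]), "central"] / p[["V"]]
}

# Michaelis-Menten elimination with first-order absorption; also tracks the
# cumulative AUC as a state
ode_mm_oracle <- function(params, dose, n_doses, times, interval = 24) {
  p <- unlist(params)
  rhs <- function(t, y, parms) {
    conc <- max(y[2] / p[["V"]], 0)
    list(c(-p[["KA"]] * y[1],
           p[["KA"]] * y[1] - p[["VMAX"]] * conc / (p[["KM"]] + conc),
           conc))
  }
  ev <- data.frame(var = "depot",
                   time = (seq_len(n_doses) - 1) * interval,
                   value = dose, method = "add")
  tt <- sort(unique(c(0, times, ev$time)))
  out <- deSolve::lsoda(c(depot = 0, central = 0, auc = 0), tt, rhs, NULL,
                        events = list(data = ev),
                        rtol = 1e-10, atol = 1e-12)
  idx <- match(times, out[, "time"])
  list(conc = out[idx, "central"] / p[["V"]], auc = out[idx, "auc"])
}

# long-format dataset builder for hand-made estimation problems
build_tk_data <- function(subjects) {
  rows <- lapply(subjects, function(s) {
    dose_times <- (seq_len(s$n_doses %||% 1) - 1) * 24
    dplyr::bind_rows(
      tibble::tibble(animal_id = s$id, cohort = "TOY",
                     dose_group = s$dose, role = "SATELLITE",
                     time = dose_times, evid = 1L, amt = s$dose,
                     dv = NA_real_, mdv = 1L),
      tibble::tibble(animal_id = s$id, cohort = "TOY",
                     dose_group = s$dose, role = "SATELLITE",
                     time = s$times, evid = 0L, amt = NA_real_,
                     dv = s$y, mdv = 0L))
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_onecmt <- c(KA = 13.46, V = 49.4, CL = 2.72)
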
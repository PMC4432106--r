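# Non-compartmental estimation of AUC24, Cmax and TAT from composite
# (pooled-mean) or serial (per-animal) profiles, with arithmetic and
# geometric summary statistics. NCA cannot extrapolate beyond the observed
# window, so the cumulative 6-month measures have no NCA analogue.

geomean <- function(x) exp(mean(log(x)))

# per-time summary of positive values under the geometric rule: zeros are
# excluded (and the contributing count decremented) rather than poisoning
# the summary
summarise_conc <- function(x, kind) {
  if (kind == "ARITHMETIC") {
    c(conc = mean(x), n = length(x))
  } else {
    pos <- x[x > 0]
    if (length(pos) == 0) c(conc = 0, n = 0) else
      c(conc = geomean(pos), n = length(pos))
  }
}

# within-day profile of one animal or a pooled group, with the t = 0 anchor:
# a pre-dose 0 on day 1, the day's own 24-h (trough) sample on steady-state
# days (the profile is periodic there)
anchor_profile <- function(times, conc, n, day) {
  times <- unname(times)
  conc <- unname(conc)
  n <- unname(n)
  if (any(abs(times) < 1e-9)) {
    ord <- order(times)
    return(tibble(time = times[ord], conc = conc[ord], n = n[ord]))
  }
  i24 <- which(abs(times - 24) < 1e-9)
  c0 <- if (day > 1 && length(i24) == 1) conc[i24] else 0
  n0 <- if (day > 1 && length(i24) == 1) n[i24] else 0L
  ord <- order(times)
  tibble(time = c(0, times[ord]), conc = c(c0, conc[ord]), n = c(n0, n[ord]))
}

#' Pooled composite mean profile for a dose group and day
#'
#' Averages the observed concentrations of the composite-sampled (toxicity)
#' animals at each scheduled sampling time, arithmetically or geometrically
#' (geometric means are taken over positive values only). Times are
#' expressed in hours after that day's dose, and the `t = 0` anchor point is
#' added: zero on day 1, the profile's own 24-h trough on later
#' (steady-state) days.
#'
#' @param ds a `tk_dataset` (or estimator view).
#' @param dose_group dose (mg/kg/day).
#' @param day sampling day (1-based).
#' @param summary_kind `"ARITHMETIC"` or `"GEOMETRIC"`.
#' @param role animal role providing the composite samples.
#' @return A `profile_summary` tibble with columns `time` (h post dose),
#'   `conc` (mg/ml) and `n` (contributing animals).
#' @export
composite_mean_profile <- function(ds, dose_group, day,
                                   summary_kind = c("ARITHMETIC",
                                                    "GEOMETRIC"),
                                   role = "TOXICITY") {
  summary_kind <- match.arg(summary_kind)
  t0 <- (day - 1) * 24
  obs <- ds[ds$evid == 0L & ds$dose_group == dose_group &
              ds$role == role & ds$time > t0 & ds$time <= t0 + 24, ]
  if (nrow(obs) == 0) abort("no observations for that dose group and day")
  rel <- obs$time - t0
  agg <- tapply(obs$dv, rel, summarise_conc, kind = summary_kind)
  times <- as.numeric(names(agg))
  mat <- do.call(rbind, agg)
  prof <- anchor_profile(times, unname(mat[, "conc"]),
                         as.integer(mat[, "n"]), day)
  structure(prof, class = c("profile_summary", class(prof)),
            summary_kind = summary_kind)
}

check_profile <- function(profile, min_points = 2) {
  if (nrow(profile) < min_points) {
    abort(paste0("insufficient data: profile has fewer than ", min_points,
                 " points"))
  }
  if (is.unsorted(profile$time, strictly = TRUE)) {
    abort("profile times must be strictly increasing")
  }
  if (any(profile$conc < 0)) abort("profile concentrations must be >= 0")
  invisible(profile)
}

#' Linear-logarithmic trapezoidal AUC
#'
#' Linear trapezoid on rising or flat segments (or segments touching zero),
#' logarithmic trapezoid `(C1 - C2) / log(C1 / C2) * dt` on strictly
#' decreasing positive segments. No extrapolation beyond the observed
#' points.
#'
#' @param profile a `profile_summary` (or any tibble with `time`, `conc`).
#' @param window integration window `c(t0, t1)` (default `c(0, 24)`),
#'   intersected with the observed time range.
#' @return AUC in mg*h/ml.
#' @examples
#' nca_auc_linlog(tibble::tibble(time = c(0, 1, 2), conc = c(0, 10, 5)))
#' @export
nca_auc_linlog <- function(profile, window = c(0, 24)) {
  check_profile(profile)
  keep <- profile$time >= window[1] & profile$time <= window[2]
  tt <- profile$time[keep]
  cc <- profile$conc[keep]
  if (length(tt) < 2) abort("insufficient data: < 2 points in window")
  auc <- 0
  for (i in seq_len(length(tt) - 1)) {
    dt <- tt[i + 1] - tt[i]
    c1 <- cc[i]
    c2 <- cc[i + 1]
    auc <- auc + if (c2 < c1 && c2 > 0 && c1 > 0) {
      (c1 - c2) / log(c1 / c2) * dt
    } else {
      (c1 + c2) / 2 * dt
    }
  }
  auc
}

#' Observed peak concentration of a summarised profile
#'
#' @param profile a `profile_summary`.
#' @return A list with `cmax` and `tmax` (ties resolved to the earliest
#'   time).
#' @export
nca_cmax <- function(profile) {
  check_profile(profile, min_points = 1)
  i <- which.max(profile$conc)  # which.max takes the earliest tie
  list(cmax = profile$conc[i], tmax = profile$time[i])
}

#' Time above a threshold concentration from a summarised profile
#'
#' The sampled profile is interpolated with the same convention as the AUC
#' rule: linear on rising segments, log-linear on strictly decreasing
#' positive segments. Threshold crossings are solved exactly on each
#' segment and the total time above the threshold inside the observed
#' window is accumulated.
#'
#' @param profile a `profile_summary`.
#' @param threshold threshold concentration (mg/ml).
#' @return Time above threshold in hours.
#' @export
nca_tat <- function(profile, threshold) {
  check_profile(profile)
  tt <- profile$time
  cc <- profile$conc
  total <- 0
  for (i in seq_len(length(tt) - 1)) {
    dt <- tt[i + 1] - tt[i]
    c1 <- cc[i]
    c2 <- cc[i + 1]
    loglin <- c2 < c1 && c2 > 0 && c1 > 0
    if (c1 > threshold && c2 > threshold) {
      total <- total + dt
    } else if (c1 <= threshold && c2 <= threshold) {
      next
    } else if (threshold <= 0) {
      # mixed segment at zero threshold: above everywhere except the single
      # endpoint where the interpolant touches zero
      total <- total + dt
    } else if (loglin) {
      # C(t) = c1 * (c2/c1)^((t - t1)/dt), down-crossing
      tstar <- tt[i] + dt * log(threshold / c1) / log(c2 / c1)
      if (c1 > threshold) total <- total + (tstar - tt[i]) else
        total <- total + (tt[i + 1] - tstar)
    } else {
      # linear segment crossing
      tstar <- tt[i] + dt * (threshold - c1) / (c2 - c1)
      if (c1 > threshold) total <- total + (tstar - tt[i]) else
        total <- total + (tt[i + 1] - tstar)
    }
  }
  total
}

#' NCA exposure from one summarised profile
#'
#' @param profile a `profile_summary`.
#' @param threshold TAT threshold (mg/ml).
#' @return A tibble with `measure` (`auc24`, `cmax24`, `tat24`) and
#'   `estimate`.
#' @export
nca_exposure_from_profile <- function(profile, threshold = 0.01) {
  tibble(measure = c("auc24", "cmax24", "tat24"),
         estimate = c(nca_auc_linlog(profile),
                      nca_cmax(profile)$cmax,
                      nca_tat(profile, threshold)))
}

#' Serial NCA: per-animal exposure averaged over the cohort
#'
#' Each serially sampled (satellite) animal's full profile on the requested
#' day gives its own AUC24, Cmax and TAT; the animal-level values are then
#' summarised arithmetically or geometrically across the cohort.
#'
#' @param ds a `tk_dataset` (or estimator view).
#' @param dose_group dose (mg/kg/day).
#' @param day sampling day.
#' @param summary_kind `"ARITHMETIC"` or `"GEOMETRIC"`.
#' @param threshold TAT threshold (mg/ml).
#' @param role animal role providing the serial profiles.
#' @return A tibble with `measure` and `estimate`.
#' @export
serial_nca_summary <- function(ds, dose_group, day,
                               summary_kind = c("ARITHMETIC", "GEOMETRIC"),
                               threshold = 0.01, role = "SATELLITE") {
  summary_kind <- match.arg(summary_kind)
  t0 <- (day - 1) * 24
  obs <- ds[ds$evid == 0L & ds$dose_group == dose_group &
              ds$role == role & ds$time > t0 & ds$time <= t0 + 24, ]
  if (nrow(obs) == 0) abort("no observations for that dose group and day")
  per_animal <- lapply(split(obs, obs$animal_id), function(a) {
    rel <- a$time - t0
    prof <- anchor_profile(rel, a$dv, rep(1L, nrow(a)), day)
    nca_exposure_from_profile(prof, threshold)$estimate
  })
  mat <- do.call(rbind, per_animal)
  est <- apply(mat, 2, function(x) {
    if (summary_kind == "ARITHMETIC") mean(x) else {
      pos <- x[x > 0]
      if (length(pos) == 0) 0 else geomean(pos)
    }
  })
  tibble(measure = c("auc24", "cmax24", "tat24"), estimate = unname(est))
}
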
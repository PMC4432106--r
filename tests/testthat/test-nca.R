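# Non-compartmental estimators: summaries, lin-log AUC, Cmax, TAT.

profile_of <- function(times, conc) {
  tibble::tibble(time = times, conc = conc, n = 1L)
}

test_that("composite summaries use arithmetic and geometric means correctly", {
  toy <- tibble::tibble(
    animal_id = rep(c("a", "b"), each = 2),
    dose_group = 30, role = "TOXICITY", evid = 0L,
    time = rep(c(1, 4), 2), dv = c(2, 3, 8, 3), mdv = 0L)
  arith <- composite_mean_profile(toy, 30, 1, "ARITHMETIC")
  expect_equal(arith$conc[arith$time == 1], 5)  # mean(2, 8)
  geo <- composite_mean_profile(toy, 30, 1, "GEOMETRIC")
  expect_equal(geo$conc[geo$time == 1], 4)      # sqrt(2 * 8)
  # day 1: a zero anchor is prepended at t = 0
  expect_equal(arith$time[1], 0)
  expect_equal(arith$conc[1], 0)

  # zeros are excluded from the geometric mean, with n decremented
  toy0 <- toy
  toy0$dv <- c(0, 3, 8, 3)
  geo0 <- composite_mean_profile(toy0, 30, 1, "GEOMETRIC")
  expect_equal(geo0$conc[geo0$time == 1], 8)
  expect_equal(geo0$n[geo0$time == 1], 1L)

  expect_error(composite_mean_profile(toy, 100, 1), "no observations")
})

test_that("lin-log trapezoidal AUC matches hand computations", {
  expect_equal(nca_auc_linlog(profile_of(c(0, 1, 2), c(0, 10, 5)),
                              window = c(0, 2)),
               5 + 5 / log(2), tolerance = 1e-12)
  expect_equal(nca_auc_linlog(profile_of(c(0, 12, 24), c(3, 3, 3))), 72)
  expect_equal(nca_auc_linlog(profile_of(c(0, 8, 24), c(0, 0, 0))), 0)
  expect_error(nca_auc_linlog(profile_of(2, 1)), "insufficient")

  # on dyadic refinements of a smooth profile the rule converges to the
  # analytic AUC
  analytic <- toxkinsim:::cpp_cum_auc(1L, ref_onecmt, 24, 30, 24, 1, 0)
  errs <- vapply(c(17, 33, 65, 129, 257), function(n) {
    tt <- seq(0, 24, length.out = n)
    cc <- predict_profile("ONE_CMT", ref_onecmt, dose_regimen(30), tt)$conc
    abs(nca_auc_linlog(profile_of(tt, cc)) - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[5], 1e-3)
})

test_that("Cmax and TAT from sampled profiles follow the interpolation rules", {
  prof <- profile_of(c(0, 1, 2), c(0, 10, 5))
  expect_equal(nca_cmax(prof)$cmax, 10)
  expect_equal(nca_cmax(prof)$tmax, 1)
  expect_equal(nca_cmax(profile_of(c(0, 1, 2), c(4, 7, 7)))$tmax, 1)
  expect_equal(nca_cmax(profile_of(3, 2.5))$cmax, 2.5)

  # lin-up/log-down crossings solved on each segment: up-crossing of 6 at
  # t = 0.6, down-crossing where 10 * 0.5^(t-1) = 6
  tat <- nca_tat(prof, 6)
  t_down <- 1 + log(0.6) / log(0.5)
  expect_equal(tat, t_down - 0.6, tolerance = 1e-12)
  expect_equal(tat, 1.137, tolerance = 1e-3)
  # brute force over the piecewise interpolant on a 1-ms grid
  interp <- function(t) {
    ifelse(t <= 1, 10 * t, 10 * 0.5^(t - 1))
  }
  brute <- sum(interp(seq(0, 2, by = 0.001)) > 6) * 0.001
  expect_lt(abs(tat - brute), 2 * 0.001)

  expect_equal(nca_tat(prof, 0), 2)
  expect_equal(nca_tat(prof, 100), 0)
})

test_that("serial NCA averages per-animal exposure over the cohort", {
  mk <- function(id, scale) {
    tibble::tibble(animal_id = id, dose_group = 30, role = "SATELLITE",
                   evid = 0L, time = c(0.5, 2, 8, 24),
                   dv = scale * c(4, 8, 3, 1), mdv = 0L)
  }
  ds <- dplyr::bind_rows(mk("a", 1), mk("b", 1), mk("c", 1))
  one <- nca_exposure_from_profile(
    toxkinsim:::anchor_profile(c(0.5, 2, 8, 24), c(4, 8, 3, 1),
                               rep(1L, 4), 1), 0.01)
  same <- serial_nca_summary(ds, 30, 1, "ARITHMETIC")
  expect_equal(same$estimate, one$estimate, tolerance = 1e-12)

  ds2 <- dplyr::bind_rows(mk("a", 0.5), mk("b", 1), mk("c", 1.5))
  m <- serial_nca_summary(ds2, 30, 1, "ARITHMETIC")
  expect_equal(m$estimate[m$measure == "cmax24"], mean(c(4, 8, 12)))
  g <- serial_nca_summary(ds2, 30, 1, "GEOMETRIC")
  expect_equal(g$estimate[g$measure == "cmax24"],
               exp(mean(log(c(4, 8, 12)))))
})

test_that("composite and serial NCA agree exactly without variability", {
  pop0 <- pop_params("ONE_CMT", theta = ref_onecmt, sigma_prop = 0)
  ds <- simulate_trial(build_cohort_design("1_WEEK"), pop0, seed = 8)
  comp <- nca_exposure_from_profile(
    composite_mean_profile(ds, 30, 1, "ARITHMETIC"), 0.01)
  ser <- serial_nca_summary(ds, 30, 1, "ARITHMETIC", 0.01)
  expect_equal(comp$estimate, ser$estimate, tolerance = 1e-12)
  # steady-state anchoring: on a later day the 24-h trough doubles as the
  # t = 0 point
  ds3 <- simulate_trial(build_cohort_design("1_MONTH"), pop0, seed = 8)
  prof28 <- composite_mean_profile(ds3, 30, 28, "ARITHMETIC")
  expect_equal(prof28$conc[prof28$time == 0],
               prof28$conc[prof28$time == 24])
})
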
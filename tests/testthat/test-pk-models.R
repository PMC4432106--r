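# Structural models, parameter sampling and residual error.

test_that("individual parameter sampling follows the log-normal BSV model", {
  pop <- default_pop_params("ONE_CMT")

  zero <- pop_params("ONE_CMT", theta = pop$theta, sigma_prop = 0)
  z <- sample_individual_params(zero, 5, seed = 1)
  for (p in names(pop$theta)) {
    expect_equal(z[[p]], rep(pop$theta[[p]], 5))
  }

  big <- sample_individual_params(pop, 10000, seed = 7)
  expect_equal(sd(log(big$CL)), 0.20, tolerance = 0.02)
  expect_equal(sd(log(big$V)), 0.16, tolerance = 0.02)
  expect_equal(sd(log(big$KA)), 0.50, tolerance = 0.02)
  expect_equal(mean(log(big$CL)), log(2.72), tolerance = 0.01)

  expect_identical(sample_individual_params(pop, 8, seed = 3),
                   sample_individual_params(pop, 8, seed = 3))

  expect_error(pop_params("ONE_CMT", theta = pop$theta,
                          bsv = c(NOTAPARAM = 10)),
               "unknown parameter")
  expect_error(pop_params("ONE_CMT",
                          theta = c(KA = 1, V = -2, CL = 1)), "> 0")
})

test_that("one-compartment prediction matches Bateman and an ODE oracle", {
  reg <- dose_regimen(30)
  ke <- ref_onecmt[["CL"]] / ref_onecmt[["V"]]
  c1 <- predict_profile("ONE_CMT", ref_onecmt, reg, 1)$conc
  bateman <- 30 * ref_onecmt[["KA"]] /
    (ref_onecmt[["V"]] * (ref_onecmt[["KA"]] - ke)) *
    (exp(-ke) - exp(-ref_onecmt[["KA"]]))
  expect_equal(c1, bateman, tolerance = 1e-12)
  expect_equal(c1, 0.577, tolerance = 1e-3)

  times <- c(0.25, 0.5, 1, 2, 6, 12, 24, 30, 47.9)
  oracle <- ode_onecmt_oracle(ref_onecmt, 30, 2, times)
  ours <- predict_profile("ONE_CMT", ref_onecmt,
                          dose_regimen(30, n_doses = 2), times)$conc
  expect_lt(max(abs(ours - oracle) / oracle), 1e-3)

  # vehicle dose and pre-dose times
  expect_equal(predict_profile("ONE_CMT", ref_onecmt, dose_regimen(0),
                               c(0, 1, 5))$conc, c(0, 0, 0))
  late <- dose_regimen(30, n_doses = 1, start_time = 10)
  expect_equal(predict_profile("ONE_CMT", ref_onecmt, late, c(0, 5, 9.9))$conc,
               c(0, 0, 0))
  expect_error(predict_profile("ONE_CMT", ref_onecmt, reg, -1), ">= 0")
})

test_that("the KA = ke degenerate case is the continuous limit", {
  p_eq <- c(KA = 0.1, V = 50, CL = 5)  # ke = CL/V = 0.1 = KA exactly
  p_near <- c(KA = 0.1 * (1 + 1e-7), V = 50, CL = 5)
  tt <- c(0.5, 2, 10, 30)
  c_eq <- predict_profile("ONE_CMT", p_eq, dose_regimen(30, n_doses = 2),
                          tt)$conc
  c_near <- predict_profile("ONE_CMT", p_near, dose_regimen(30, n_doses = 2),
                            tt)$conc
  expect_lt(max(abs(c_eq - c_near) / c_eq), 1e-5)
  # analytic limit D*KA*t*exp(-KA t)/V for a single dose
  expect_equal(predict_profile("ONE_CMT", p_eq, dose_regimen(30), 2)$conc,
               30 * 0.1 * 2 * exp(-0.2) / 50, tolerance = 1e-10)
})

test_that("two-compartment prediction matches an ODE oracle and AUC theory", {
  p <- unlist(default_pop_params("TWO_CMT")$theta)
  rhs <- function(t, y, parms) {
    list(c(-p[["KA"]] * y[1],
           p[["KA"]] * y[1] - (p[["CL"]] / p[["V"]] + p[["K12"]]) * y[2] +
             p[["K21"]] * y[3],
           p[["K12"]] * y[2] - p[["K21"]] * y[3]))
  }
  ev <- data.frame(var = "depot", time = c(0, 24, 48), value = 30,
                   method = "add")
  tt <- c(0, 1, 6, 24, 30, 60)
  out <- deSolve::lsoda(c(depot = 0, central = 0, periph = 0),
                        sort(unique(c(tt, ev$time))), rhs, NULL,
                        events = list(data = ev), rtol = 1e-10, atol = 1e-12)
  oracle <- out[match(tt, out[, "time"]), "central"] / p[["V"]]
  ours <- predict_profile("TWO_CMT", p, dose_regimen(30, n_doses = 3),
                          tt)$conc
  expect_lt(max(abs(ours[-1] - oracle[-1]) / oracle[-1]), 1e-3)

  # AUC to infinity is D/CL regardless of distribution; with K12 = K21 it
  # also matches the one-compartment model with the same clearance
  p_eq <- c(KA = 1, V = 50, CL = 2.5, K12 = 0.2, K21 = 0.2)
  auc_inf <- toxkinsim:::cpp_cum_auc(3L, p_eq, 1e5, 30, 24, 1, 0)
  expect_equal(auc_inf, 30 / 2.5, tolerance = 1e-8)
  auc_1c <- toxkinsim:::cpp_cum_auc(1L, c(KA = 1, V = 50, CL = 2.5),
                                    1e5, 30, 24, 1, 0)
  expect_equal(auc_inf, auc_1c, tolerance = 1e-8)
})

test_that("superposition holds exactly for the linear models", {
  for (m in c("ONE_CMT", "TWO_CMT")) {
    p <- unlist(default_pop_params(m)$theta)
    tt <- c(1, 12, 25, 49, 80, 119.5)
    multi <- predict_profile(m, p, dose_regimen(30, n_doses = 5), tt)$conc
    single <- rowSums(sapply(0:4, function(k) {
      predict_profile(m, p, dose_regimen(30, n_doses = 1,
                                         start_time = 24 * k), tt)$conc
    }))
    expect_lt(max(abs(multi - single) / pmax(multi, 1e-12)), 1e-8)
  }
})

test_that("Michaelis-Menten model: ODE oracle, linear limit, mass balance", {
  p <- unlist(default_pop_params("ONE_CMT_MM")$theta)
  tt <- c(0.1, 0.4, 1, 1.5, 4, 8, 24, 47.9, 71)
  oracle <- ode_mm_oracle(p, 100, 3, tt)
  ours <- predict_profile("ONE_CMT_MM", p, dose_regimen(100, n_doses = 3),
                          tt)$conc
  expect_lt(max(abs(ours - oracle$conc) / oracle$conc), 1e-4)

  # at C << Km the model collapses to first-order elimination with
  # CL = VMAX/KM (= 2.72 here)
  lin <- predict_profile("ONE_CMT", c(KA = p[["KA"]], V = p[["V"]],
                                      CL = p[["VMAX"]] / p[["KM"]]),
                         dose_regimen(0.01, n_doses = 2), tt)$conc
  mm <- predict_profile("ONE_CMT_MM", p, dose_regimen(0.01, n_doses = 2),
                        tt)$conc
  expect_lt(max(abs(mm - lin) / lin), 1e-3)

  # mass balance at every grid point: dosed = depot + body + eliminated
  sol <- toxkinsim:::cpp_mm_profile(p, seq(0.5, 72, by = 0.5), 100, 24, 3,
                                    0, 1e-8, 1e-10)
  balance <- sol$dosed - (sol$depot + sol$conc * p[["V"]] + sol$eliminated)
  expect_lt(max(abs(balance)) / 100, 1e-6)
})

test_that("dose proportionality holds for linear kinetics and fails for MM", {
  lin10 <- exposure_from_params("ONE_CMT", ref_onecmt, 10, 7,
                                measures = "auc24")$auc24
  lin100 <- exposure_from_params("ONE_CMT", ref_onecmt, 100, 7,
                                 measures = "auc24")$auc24
  expect_equal(lin100 / lin10, 10, tolerance = 1e-8)

  p_mm <- unlist(default_pop_params("ONE_CMT_MM")$theta)
  mm10 <- exposure_from_params("ONE_CMT_MM", p_mm, 10, 7,
                               horizon_days = 7, measures = "auc24")$auc24
  mm100 <- exposure_from_params("ONE_CMT_MM", p_mm, 100, 7,
                                horizon_days = 7, measures = "auc24")$auc24
  expect_gt(mm100 / mm10, 10)
})

test_that("proportional residual error behaves as specified", {
  expect_equal(simulate_observations(c(1, 2, 0.5), sigma = 0), c(1, 2, 0.5))
  obs <- simulate_observations(rep(1, 1e5), sigma = 0.15, seed = 42)
  expect_equal(sd(obs), 0.15, tolerance = 0.01)
  expect_equal(mean(obs), 1, tolerance = 0.005)
  expect_equal(simulate_observations(rep(0, 10), sigma = 0.15, seed = 1),
               rep(0, 10))
  expect_error(simulate_observations(1, sigma = -0.1), ">= 0")
  expect_true(all(simulate_observations(rep(0.01, 1e4), sigma = 2,
                                        seed = 9) >= 0))
})
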
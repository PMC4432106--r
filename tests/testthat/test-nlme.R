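# The FOCE-I estimator: conditional modes, objective, fitting and the
# covariance step.

test_that("FOCE objective equals the exact Gaussian marginal for eta-linear models", {
  # constant-mean model, additive random effect and additive error: the
  # marginal is Gaussian with covariance sigma^2 I + omega^2 J
  subjects <- list(
    list(id = "a", dose = 1, times = c(1, 2, 3), y = c(9.5, 10.5, 10.2)),
    list(id = "b", dose = 1, times = c(1, 2), y = c(11.0, 9.8)),
    list(id = "c", dose = 1, times = 4, y = c(10.9)))
  data <- build_tk_data(subjects)
  mu <- 10.2
  omega <- 0.4
  sigma <- 0.3
  res <- focei_ofv(data, "ETA_LINEAR", theta = c(MU = mu),
                   omega_sd = c(MU = omega), sigma = sigma,
                   error = "additive")
  exact <- sum(vapply(subjects, function(s) {
    n <- length(s$y)
    S <- sigma^2 * diag(n) + omega^2 * matrix(1, n, n)
    r <- s$y - mu
    n * log(2 * pi) + determinant(S)$modulus +
      drop(r %*% solve(S, r))
  }, numeric(1)))
  expect_equal(res$ofv, exact, tolerance = 1e-8)

  # duplicating every subject exactly doubles the objective
  dup <- build_tk_data(c(subjects, lapply(subjects, function(s) {
    s$id <- paste0(s$id, "2")
    s
  })))
  res2 <- focei_ofv(dup, "ETA_LINEAR", theta = c(MU = mu),
                    omega_sd = c(MU = omega), sigma = sigma,
                    error = "additive")
  expect_equal(res2$ofv, 2 * res$ofv, tolerance = 1e-10)
})

test_that("conditional modes shrink to zero as Omega vanishes and recover a known eta", {
  subjects <- list(list(id = "a", dose = 1, times = c(1, 2, 3),
                        y = c(9.5, 10.5, 10.2)))
  data <- build_tk_data(subjects)
  tiny <- conditional_etas(data, "ETA_LINEAR", theta = c(MU = 10),
                           omega_sd = c(MU = 1e-5), sigma = 0.3,
                           error = "additive")
  expect_lt(abs(tiny$etas[1, 1]), 1e-6)
  expect_true(all(tiny$ok))
  expect_equal(dim(tiny$curvature[[1]]), c(1, 1))
  expect_gt(tiny$curvature[[1]][1, 1], 0)

  # round trip: simulate one subject with a known eta and rich noise-free
  # data; the conditional mode must recover it
  eta_true <- c(KA = 0.35, V = -0.10, CL = 0.22)
  p_i <- ref_onecmt * exp(eta_true)
  tt <- seq(0.2, 24, length.out = 25)
  y <- predict_profile("ONE_CMT", p_i, dose_regimen(30), tt)$conc
  data_pk <- build_tk_data(list(list(id = "s1", dose = 30, times = tt,
                                     y = y)))
  ce <- conditional_etas(data_pk, "ONE_CMT", theta = ref_onecmt,
                         omega_sd = c(KA = 0.5, V = 0.16, CL = 0.2),
                         sigma = 1e-3)
  expect_equal(unname(ce$etas[1, ]), unname(eta_true), tolerance = 1e-2)

  # a subject whose observations were all removed is excluded with a
  # warning, not an error
  lone <- build_tk_data(list(list(id = "s1", dose = 30, times = tt, y = y),
                             list(id = "s2", dose = 30, times = 1,
                                  y = NA_real_)))
  expect_warning(focei_ofv(lone, "ONE_CMT", theta = ref_onecmt,
                           omega_sd = c(KA = 0.5, V = 0.16, CL = 0.2),
                           sigma = 0.15),
                 "excluded")
})

test_that("noise-free, BSV-free data recovers the generating parameters", {
  pop0 <- pop_params("ONE_CMT", theta = ref_onecmt, sigma_prop = 0)
  ds <- simulate_trial(build_cohort_design("1_WEEK"), pop0, seed = 5)
  fit <- fit_population(estimator_view(apply_bql_filter(ds)), pop0,
                        perturb = 1.5)
  expect_lt(max(abs(fit$theta - ref_onecmt) / ref_onecmt), 1e-3)
  # model-based exposure from the recovered fit equals the truth
  e_fit <- exposure_from_fit(fit, 30, 1)
  e_true <- exposure_from_params("ONE_CMT", ref_onecmt, 30, 1)
  expect_equal(e_fit$auc24, e_true$auc24, tolerance = 1e-3)
  expect_equal(e_fit$cmax24, e_true$cmax24, tolerance = 1e-3)
})

test_that("estimation sees only the estimator-facing view of the data", {
  pop <- default_pop_params("ONE_CMT")
  ds <- simulate_trial(build_cohort_design("1_WEEK"), pop, seed = 14)
  dsf <- apply_bql_filter(ds)
  corrupted <- dsf
  corrupted$dv_true <- corrupted$dv_true * 1000
  f1 <- fit_population(estimator_view(dsf), pop)
  f2 <- fit_population(corrupted, pop)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$ofv, f2$ofv)
})

test_that("the covariance step reflects objective curvature honestly", {
  # quadratic oracle: objective (p - m)' A (p - m) as a -2 log-likelihood
  # has covariance 2 A^{-1} at the minimum
  A <- matrix(c(4, 1, 1, 3), 2, 2)
  m <- c(1, 2)
  fn <- function(p) drop(t(p - m) %*% A %*% (p - m))
  hs <- toxkinsim:::hessian_se(fn, m)
  expect_true(hs$ok)
  expect_equal(unname(hs$se), sqrt(diag(solve(A))), tolerance = 1e-6)

  # a saddle is detected as a failed covariance step
  saddle <- function(p) p[1]^2 - p[2]^2
  expect_false(toxkinsim:::hessian_se(saddle, c(0, 0))$ok)

  # a non-converged fit never reports a usable covariance, and wildly
  # wrong starting values either reach the optimum or say so honestly
  pop <- default_pop_params("ONE_CMT")
  ds <- simulate_trial(build_cohort_design("1_WEEK"), pop, seed = 15)
  fit <- fit_population(estimator_view(apply_bql_filter(ds)), pop,
                        run_covariance = FALSE)
  flagged <- fit
  flagged$converged <- FALSE
  flagged <- covariance_step(flagged)
  expect_false(flagged$covariance_ok)

  far <- fit_population(estimator_view(apply_bql_filter(ds)), pop,
                        perturb = 100)
  expect_true(far$converged || !far$covariance_ok)
  if (far$converged) {
    expect_lt(abs(far$theta[["CL"]] - 2.72) / 2.72, 0.25)
  }
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  pop <- default_pop_params("ONE_CMT")
  fit_for <- function(n_sat, seed) {
    des <- build_cohort_design("1_WEEK", satellite_n = n_sat,
                               toxicity_n = 3)
    ds <- simulate_trial(des, pop, seed = seed)
    fit_population(estimator_view(apply_bql_filter(ds)), pop)
  }
  small <- fit_for(3, 31)
  large <- fit_for(12, 31)
  expect_true(small$covariance_ok && large$covariance_ok)
  # subjects grow from 6 to 15 per active group: expect a clear (not
  # exact) 1/sqrt(n) reduction in the CL standard error
  ratio <- small$se[["theta_CL"]] / large$se[["theta_CL"]]
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 3)
})
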
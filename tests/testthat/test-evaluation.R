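# Bias/precision metrics and the replicate-study orchestration.

test_that("SMRE, CV and relative error implement the study formulas", {
  expect_equal(smre(c(100, 100, 100), 100), 0)
  expect_equal(smre(120, 100), 20)
  expect_equal(smre(c(80, 120), 100), 0)
  expect_error(smre(c(1, 2), 0), "zero")

  expect_equal(relative_error(11, 10), 10)
  expect_equal(relative_error(5, 10), -50)
  expect_equal(relative_error(10, 10), 0)

  expect_equal(cv_precision(c(5, 5, 5)), 0)
  # printed formula: 1/N * sqrt(sum(((x - mean)/mean)^2)) * 100
  expect_equal(cv_precision(c(90, 110)), 0.5 * sqrt(0.02) * 100,
               tolerance = 1e-12)
  expect_equal(cv_precision(c(90, 110)), 7.071, tolerance = 1e-3)
  # duplicating the sample shrinks the replicate-formula CV by 1/sqrt(2)
  x <- c(90, 95, 100, 112)
  expect_equal(cv_precision(rep(x, 2)), cv_precision(x) / sqrt(2),
               tolerance = 1e-12)
  # the conventional sample CV is invariant under duplication (up to the
  # n-1 denominator)
  expect_equal(cv_precision(x, "sample"), sd(x) / mean(x) * 100)
  expect_error(cv_precision(c(-1, 1)), "zero")
})

test_that("the noise-free limit gives zero bias and spread for model estimates", {
  pop0 <- pop_params("ONE_CMT", theta = ref_onecmt, sigma_prop = 0)
  cfg <- scenario_config(model = "ONE_CMT", duration = "1_WEEK",
                         dose_group = 30, n_replicates = 2,
                         master_seed = 7, methods = "model",
                         measures = c("auc24", "cmax24"),
                         init_perturb = 1, pop = pop0)
  st <- run_study(cfg)
  cmp <- tidy(st)
  expect_lt(max(abs(cmp$smre)), 0.1)
  expect_lt(max(cmp$cv), 0.1)
})

test_that("replicate studies are deterministic and internally consistent", {
  cfg <- scenario_config(model = "ONE_CMT", duration = "1_WEEK",
                         dose_group = 30, n_replicates = 3,
                         master_seed = 11,
                         methods = c("model", "nca_serial_mean"),
                         measures = c("auc24", "cmax24", "tat24"))
  st1 <- run_study(cfg)
  st2 <- run_study(cfg)
  expect_identical(as.data.frame(tidy(st1)), as.data.frame(tidy(st2)))
  expect_identical(st1$results$estimate, st2$results$estimate)

  # SMRE equals the mean of the per-replicate relative errors
  cmp <- tidy(st1)
  for (i in seq_len(nrow(cmp))) {
    rows <- st1$results[st1$results$method == cmp$method[i] &
                          st1$results$measure == cmp$measure[i], ]
    rows <- rows[!is.na(rows$estimate) &
                   (is.na(rows$converged) | rows$converged), ]
    expect_equal(cmp$smre[i],
                 mean((rows$estimate - rows$truth) / rows$truth * 100),
                 tolerance = 1e-10)
  }
  # quantile rows are ordered
  expect_true(all(cmp$q05 <= cmp$q25 & cmp$q25 <= cmp$q50 &
                    cmp$q50 <= cmp$q75 & cmp$q75 <= cmp$q95))

  # written tables round-trip
  dir <- tempfile()
  files <- write_study_tables(st1, dir)
  back <- readr::read_csv(files[["comparison"]], show_col_types = FALSE)
  expect_equal(back$smre, cmp$smre, tolerance = 1e-9)
  expect_equal(nrow(readr::read_csv(files[["replicates"]],
                                    show_col_types = FALSE)),
               nrow(st1$results))
})

test_that("configs reject invalid input and round-trip through YAML", {
  expect_error(scenario_config(methods = character(0)))
  expect_error(scenario_config(n_replicates = 0), "n_replicates")
  expect_error(scenario_config(dose_group = 55), "dose_group")

  cfg <- scenario_config(model = "TWO_CMT", duration = "1_MONTH",
                         n_replicates = 4, master_seed = 99,
                         lloq = 0.002, threshold = 0.02)
  f <- tempfile(fileext = ".yaml")
  write_scenario(cfg, f)
  back <- read_scenario(f)
  expect_equal(back$model, "TWO_CMT")
  expect_equal(back$n_replicates, 4L)
  expect_equal(back$lloq, 0.002)
  expect_equal(back$pop$theta, cfg$pop$theta)
  expect_equal(back$pop$bsv, cfg$pop$bsv)
})

test_that("study plots are well-formed ggplot objects", {
  cfg <- scenario_config(model = "ONE_CMT", duration = "1_WEEK",
                         dose_group = 30, n_replicates = 2,
                         master_seed = 13, methods = "nca_serial_mean",
                         measures = c("auc24", "cmax24"))
  st <- run_study(cfg)
  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
  pop <- default_pop_params("ONE_CMT")
  ds <- simulate_trial(build_cohort_design("1_WEEK"), pop, seed = 2)
  fit <- fit_population(estimator_view(apply_bql_filter(ds)), pop)
  expect_s3_class(autoplot(fit), "ggplot")
  aug <- augment(fit)
  expect_true(all(c(".pred", ".ipred", ".resid") %in% names(aug)))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_s3_class(glance(fit), "tbl_df")
})
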
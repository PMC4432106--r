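# The synthetic-trial stage: record bookkeeping, reproducibility, the BQL
# filter and the CSV dialect.

test_that("simulated observation counts match the design's scheduled slots", {
  pop <- default_pop_params("ONE_CMT")
  des <- build_cohort_design("1_WEEK")
  ds <- simulate_trial(des, pop, seed = 9)

  obs <- ds[ds$evid == 0L, ]
  # satellite serial, active groups: 3 animals x 3 dose groups x 7 times
  expect_equal(nrow(obs[obs$role == "SATELLITE" & obs$dose_group > 0, ]), 63)
  # every group (incl. vehicle) contributes 21 composite + 21 serial slots
  expect_equal(nrow(obs), 4 * (21 + 21))
  # composite day: each scheduled time covered by 3 distinct toxicity animals
  tox <- obs[obs$role == "TOXICITY" & obs$dose_group == 30, ]
  per_time <- split(tox$animal_id, tox$time)
  expect_true(all(vapply(per_time, function(x) {
    length(x) == 3 && !anyDuplicated(x)
  }, logical(1))))
  # dose records: one per animal per day
  doses <- ds[ds$evid == 1L, ]
  expect_equal(nrow(doses), (4 + 3) * 4 * 7)

  expect_equal(obs$dv[obs$dose_group == 0], rep(0, 42))

  ds2 <- simulate_trial(des, pop, seed = 9)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))
  ds3 <- simulate_trial(des, pop, seed = 10)
  expect_false(identical(ds$dv, ds3$dv))
})

test_that("between-animal variability in day-1 Cmax reflects the BSV model", {
  pop <- default_pop_params("ONE_CMT")
  ani <- sample_individual_params(pop, 500, seed = 21)
  cmax <- vapply(seq_len(500), function(i) {
    exposure_from_params("ONE_CMT", unlist(ani[i, c("KA", "V", "CL")]),
                         30, 1, measures = "cmax24")$cmax24
  }, numeric(1))
  # independent linearisation oracle: CV of log Cmax from numerical
  # sensitivities of log Cmax to log parameters at the typical values
  sens <- vapply(c("KA", "V", "CL"), function(p) {
    th_p <- pop$theta
    th_m <- pop$theta
    th_p[[p]] <- th_p[[p]] * exp(0.01)
    th_m[[p]] <- th_m[[p]] * exp(-0.01)
    (log(exposure_from_params("ONE_CMT", th_p, 30, 1,
                              measures = "cmax24")$cmax24) -
       log(exposure_from_params("ONE_CMT", th_m, 30, 1,
                                measures = "cmax24")$cmax24)) / 0.02
  }, numeric(1))
  omega <- pop$bsv[c("KA", "V", "CL")] / 100
  implied <- sqrt(sum((sens * omega)^2))
  expect_equal(sd(log(cmax)), implied, tolerance = 0.15)
})

test_that("the BQL filter omits below-limit observations only", {
  pop <- default_pop_params("ONE_CMT")
  des <- build_cohort_design("1_WEEK")
  ds <- simulate_trial(des, pop, seed = 4)

  filt0 <- apply_bql_filter(ds, lloq = 0)
  expect_equal(nrow(filt0), nrow(ds))
  expect_equal(filt0$dv, ds$dv)

  toy <- ds[ds$evid == 0L, ][1:3, ]
  toy$dv <- c(0.5, 0.005, 0.02)
  kept <- apply_bql_filter(toy, lloq = 0.01)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_bql_removed"), 1L)

  # vehicle observations (exact zeros) fall below any positive limit
  filt <- apply_bql_filter(ds, lloq = 1e-9)
  expect_equal(sum(filt$evid == 0 & filt$dose_group == 0), 0)
  expect_equal(sum(filt$evid == 1), sum(ds$evid == 1))
  # at the default limit nothing is censored in the reference scenarios
  expect_equal(attr(apply_bql_filter(ds[ds$dose_group > 0, ], 0.001),
                    "n_bql_removed"), 0L)
})

test_that("the long-format CSV dialect round-trips byte for byte", {
  pop <- default_pop_params("ONE_CMT")
  ds <- simulate_trial(build_cohort_design("1_WEEK"), pop, seed = 6)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_tk_csv(ds, f1, keep_truth = TRUE)
  back <- read_tk_csv(f1)
  write_tk_csv(back, f2, keep_truth = TRUE)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$dv, ds$dv)

  ev <- estimator_view(ds)
  expect_false("dv_true" %in% names(ev))
  expect_null(attr(ev, "animals"))
  expect_false(is.null(attr(ds, "animals")))
})
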
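test_that("noise-free dense digitization equals the exact KM step function", {
  sim <- simulate_km(surv_dist("weibull", shape = 1.4, scale = 6), 80,
                     grid_step = 0.1, jitter_sd = 0, seed = 1)
  km <- km_estimate(sim$ipd)
  expect_equal(sim$curve$survival, km_surv_at(km, sim$curve$time),
               tolerance = 1e-12)
  expect_equal(sim$risk$n_risk[1], 80)
})

test_that("simulated cohorts reproduce the analytic median", {
  sim <- simulate_km(surv_dist("lognormal", meanlog = 1.414933,
                               sdlog = 0.958343), 200,
                     grid_step = 0.25, seed = 12)
  emp_med <- stats::median(sim$ipd$time)
  expect_lt(abs(emp_med - exp(1.414933)), 0.5)
})

test_that("digitizer jitter keeps the curve a valid survival function", {
  sim <- simulate_km(surv_dist("gamma", shape = 1.8, rate = 0.25), 150,
                     grid_step = 0.5, jitter_sd = 0.02, seed = 3)
  s <- sim$curve$survival
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("risk table counts subjects still under observation", {
  sim <- simulate_km(surv_dist("weibull", shape = 1.2, scale = 10), 60,
                     censoring = list(mechanism = "admin", rate = 12),
                     grid_step = 2, seed = 9)
  expect_equal(sim$risk$n_risk[1], 60)
  expect_true(all(diff(sim$risk$n_risk) <= 0))
  # administrative cutoff: nobody observed beyond 12 months
  expect_lte(max(sim$ipd$time), 12)
})

test_that("the full pipeline recovers the generating family end to end", {
  sim <- simulate_km(surv_dist("lognormal", meanlog = 1.63382, sdlog = 1.03730),
                     5000, censoring = list(mechanism = "uniform", rate = 0.1),
                     grid_step = 0.25, jitter_sd = 0.002, seed = 2024)
  ipd <- reconstruct_ipd(sim$curve, sim$risk)
  fits <- fit_all_families(ipd)
  best <- select_best(fits)
  expect_equal(best$dist$family, "lognormal")
  expect_lt(abs(best$dist$params["meanlog"] - 1.63382), 0.1)
  expect_lt(abs(best$dist$params["sdlog"] - 1.03730), 0.1)
})

test_that("the bundled model pins every published parameter", {
  m <- default_model()
  expect_silent(validate_model(m))
  pins <- list(
    "utilities.pf" = 0.837, "utilities.pd" = 0.443,
    "drugs.ELA.unit_cost" = 2.175, "drugs.FUL.unit_cost" = 3.915,
    "drugs.anastrozole.unit_cost" = 0.107,
    "drugs.letrozole.unit_cost" = 0.106,
    "drugs.exemestane.unit_cost" = 0.713,
    "costs.after_progression" = 6549, "costs.subsequent" = 9061,
    "costs.end_of_life" = 2601, "costs.follow_up" = 2959,
    "costs.administration" = 702,
    "costs.ae.nausea" = 2586, "costs.ae.back_pain" = 2501,
    "ae_risks.ELA.nausea" = 0.025, "ae_risks.ELA.back_pain" = 0.025,
    "ae_risks.SOC.nausea" = 0.009, "ae_risks.SOC.back_pain" = 0.004,
    "ae_risks.FUL.back_pain" = 0.006,
    "disutilities.nausea" = 0.05, "disutilities.back_pain" = 0.07,
    "config.annual_discount" = 0.03, "wtp" = 150000)
  for (id in names(pins)) {
    expect_equal(get_parameter(m, id), pins[[id]], label = id)
  }
  # survival parameter pins (one per block)
  expect_equal(m$survival$overall$pfs$ELA$params,
               c(meanlog = 1.414933, sdlog = 0.958343))
  expect_equal(m$survival$overall$os$SOC$params,
               c(meanlog = 3.09129, sdlog = 1.09301))
  expect_equal(m$survival$esr1$pfs$FUL$params,
               c(shape = 2.40911, scale = 2.63315))
  expect_equal(m$survival$esr1$os$ELA$params,
               c(meanlog = 3.339774, sdlog = 0.858537))
  # standard-of-care mixture weights
  w <- vapply(m$strategies$SOC$components, `[[`, numeric(1), "weight")
  expect_equal(w, c(0.6933, 0.1022, 0.1022, 0.1022))
  expect_equal(sum(w), 0.9999, tolerance = 1e-9)
})

test_that("the model config round-trips through JSON", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$utilities, m$utilities)
  expect_equal(m2$survival$overall$pfs$ELA$params,
               m$survival$overall$pfs$ELA$params)
  expect_equal(m2$config$treatment_duration, m$config$treatment_duration)
  expect_equal(run_cea(m2, "overall")$incremental$icer,
               run_cea(m, "overall")$incremental$icer)
})

test_that("validation errors name the offending field", {
  m <- default_model()
  m$utilities$pf <- 1.4
  expect_error(validate_model(m), "utilities.pf")
  m <- default_model()
  m$utilities <- NULL
  expect_error(validate_model(m), "utilities")
  m <- default_model()
  m$strategies$SOC$components[[1]]$weight <- 0.9
  expect_error(validate_model(m), "strategies.SOC")
  m <- default_model()
  m$costs$follow_up <- -10
  expect_error(validate_model(m), "nonnegative")
})
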
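overall_curves <- function() {
  m <- default_model()
  list(pfs = m$survival$overall$pfs$ELA, os = m$survival$overall$os$ELA)
}

test_that("occupancy starts at (1, 0, 0) and partitions the cohort", {
  cv <- overall_curves()
  cfg <- psm_config(half_cycle = FALSE)
  tr <- compute_occupancy(cv$pfs, cv$os, cfg)
  expect_equal(unlist(tr[1, c("pf", "pd", "dead")]), c(pf = 1, pd = 0, dead = 0))
  expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-12))
  expect_true(all(diff(tr$dead) >= -1e-12))
})

test_that("identical PFS and OS curves leave nobody in progressed disease", {
  cv <- overall_curves()
  tr <- compute_occupancy(cv$os, cv$os, psm_config())
  expect_true(all(tr$pd == 0))
})

test_that("a PFS curve above OS is clipped with a warning, not an error", {
  cv <- overall_curves()
  expect_warning(tr <- compute_occupancy(cv$os, cv$pfs, psm_config()),
                 "clipping")
  expect_true(all(tr$pf <= 1 - tr$dead + 1e-12))
})

test_that("terminal mortality equals the survival-function complement", {
  # frozen oracle: pnorm((log(120) - 3.192779)/0.851157) = 0.969506
  cv <- overall_curves()
  cfg <- psm_config(n_cycles = 121, half_cycle = FALSE)
  tr <- compute_occupancy(cv$pfs, cv$os, cfg)
  expect_equal(tr$dead[121], 0.969506, tolerance = 1e-5)
  expect_equal(tr$time[121], 120)
})

test_that("background mortality floors overall survival", {
  cv <- overall_curves()
  cfg <- psm_config(background_annual_mortality = 0.2)
  tr <- compute_occupancy(cv$pfs, cv$os, cfg)
  s_bg <- (1 - 0.2)^(tr$time / 12)
  expect_true(all(1 - tr$dead <= s_bg + 1e-12))
})

test_that("with unit utilities, no AEs and no discount, QALYs equal LYs", {
  m <- neutral_model()
  res <- run_cea(m, "overall")
  expect_equal(res$summary$total_qalys, res$summary$total_lys, tolerance = 1e-12)
})

test_that("the discount factor at one year is 1/1.03", {
  cv <- overall_curves()
  cfg <- psm_config(n_cycles = 13, half_cycle = FALSE)
  tr <- compute_occupancy(cv$pfs, cv$os, cfg)
  expect_equal(tr$discount[tr$time == 12], 1 / 1.03, tolerance = 1e-12)
})

test_that("discounted totals never exceed undiscounted ones", {
  m <- default_model()
  m0 <- m; m0$config$annual_discount <- 0
  r <- run_cea(m, "overall"); r0 <- run_cea(m0, "overall")
  expect_true(all(r$summary$total_cost <= r0$summary$total_cost))
  expect_true(all(r$summary$total_qalys <= r0$summary$total_qalys))
})

test_that("end-of-life spending telescopes below a single payment", {
  m <- default_model()
  res <- run_cea(m, "overall")
  tr <- res$traces$ELA
  eol <- sum(tr$death_incident * m$costs$end_of_life * tr$discount)
  expect_lte(eol, m$costs$end_of_life)
  # brute-force per-cycle oracle
  brute <- 0
  prev_dead <- 0
  for (i in seq_len(nrow(tr))) {
    brute <- brute + (tr$dead[i] - prev_dead) * m$costs$end_of_life * tr$discount[i]
    prev_dead <- tr$dead[i]
  }
  expect_equal(eol, brute, tolerance = 1e-9)
})

test_that("identical strategies yield zero increments and an undefined ICER", {
  m <- default_model()
  m$survival$overall$pfs$SOC <- m$survival$overall$pfs$ELA
  m$survival$overall$os$SOC <- m$survival$overall$os$ELA
  m$strategies$SOC <- m$strategies$ELA
  res <- run_cea(m, "overall", strategies = c("ELA", "SOC"))
  expect_equal(res$incremental$incr_cost, 0)
  expect_equal(res$incremental$incr_qalys, 0)
  expect_true(is.na(res$incremental$icer))
  expect_match(res$incremental$note, "undefined")
})

test_that("dominance is flagged instead of dividing by signs", {
  expect_equal(icer(5, 0.1)$note, "ok")
  expect_equal(icer(-5, 0.1)$note, "dominant")
  expect_equal(icer(5, -0.1)$note, "dominated")
  expect_true(is.na(icer(5, -0.1)$icer))
  expect_true(is.na(icer(5, 0)$icer))
})

test_that("raising a utility or a unit cost moves totals monotonically", {
  m <- default_model()
  base <- run_cea(m, "overall")$summary
  up_u <- set_parameter(m, "utilities.pd", 0.5)
  expect_true(all(run_cea(up_u, "overall")$summary$total_qalys >=
                    base$total_qalys))
  up_c <- set_parameter(m, "costs.follow_up", 4000)
  expect_true(all(run_cea(up_c, "overall")$summary$total_cost >=
                    base$total_cost))
})

test_that("refining the cycle grid changes totals continuously", {
  m <- default_model()
  monthly <- run_cea(m, "overall")$summary
  m$config$cycle_length <- 0.25
  m$config$n_cycles <- 480
  # scale per-cycle charges to the shorter cycle
  m$config$days_per_cycle <- 30 / 4
  for (f in c("after_progression", "subsequent", "follow_up"))
    m$costs[[f]] <- m$costs[[f]] / 4
  m$drugs$FUL$cycle1_admins <- 2   # loading unchanged: falls in first cycles
  fine <- run_cea(m, "overall")$summary
  expect_equal(fine$total_qalys, monthly$total_qalys, tolerance = 0.02)
  expect_equal(fine$total_lys, monthly$total_lys, tolerance = 0.02)
})
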
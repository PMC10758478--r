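test_that("degenerate ranges reproduce the base-case ICER exactly", {
  m <- default_model()
  base <- run_cea(m, "overall")$incremental$icer
  specs <- data.frame(id = c("utilities.pf", "costs.follow_up"))
  specs$low <- specs$high <- vapply(specs$id, function(id)
    get_parameter(m, id), numeric(1))
  torn <- one_way_dsa(m, "overall", specs)
  expect_equal(torn$icer_at_low, rep(base, 2))
  expect_equal(torn$icer_at_high, rep(base, 2))
  expect_equal(torn$spread, c(0, 0))
})

test_that("parameters outside the compared strategies have zero spread", {
  m <- default_model()
  torn <- one_way_dsa(m, "overall",  # headline comparison is ELA vs SOC
                      data.frame(id = "ae_risks.FUL.back_pain",
                                 low = 0, high = 0.5))
  expect_equal(torn$spread, 0)
  expect_error(one_way_dsa(m, "overall",
                           data.frame(id = "no.such.param", low = 0, high = 1)),
               "unknown parameter")
})

test_that("the ICER rises monotonically with the intervention drug price", {
  m <- default_model()
  prices <- seq(1.088, 2.610, length.out = 5)
  icers <- vapply(prices, function(p) {
    run_cea(set_parameter(m, "drugs.ELA.unit_cost", p),
            "overall")$incremental$icer
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("tornado is sorted by spread and discounting obeys its inequality", {
  m <- default_model()
  torn <- one_way_dsa(m, "overall")
  expect_true(all(diff(torn$spread) <= 1e-9))
  q0 <- run_cea(set_parameter(m, "config.annual_discount", 0),
                "overall")$summary$total_qalys
  q5 <- run_cea(set_parameter(m, "config.annual_discount", 0.05),
                "overall")$summary$total_qalys
  expect_true(all(is.finite(q0)) && all(is.finite(q5)))
  expect_true(all(q0 >= q5))
})

test_that("probabilistic draws are moment-matched to the base values", {
  m <- default_model()
  set.seed(99)
  draws <- draw_psa_parameters(m, 10000)
  expect_equal(mean(draws[, "utilities.pf"]), 0.837, tolerance = 0.005 / 0.837)
  expect_equal(mean(draws[, "costs.subsequent"]), 9061, tolerance = 0.01)
  expect_true(all(draws[, "utilities.pf"] >= 0 & draws[, "utilities.pf"] <= 1))
  expect_true(all(draws[, "costs.subsequent"] >= 0))
  # the discount rate is not varied probabilistically
  expect_true(all(draws[, "config.annual_discount"] == 0.03))
})

test_that("a zero-width range collapses to the base value", {
  m <- default_model()
  m$ranges <- data.frame(id = "utilities.pd", low = 0.443, high = 0.443,
                         kind = "utility")
  draws <- draw_psa_parameters(m, 50)
  expect_true(all(draws[, "utilities.pd"] == 0.443))
})

test_that("an infeasible beta moment match falls back to the range with a warning", {
  m <- default_model()
  m$ranges <- data.frame(id = "ae_risks.ELA.nausea", low = 0, high = 1,
                         kind = "prob")  # sd 0.255 >> feasible for mean 0.025
  set.seed(5)
  expect_warning(draws <- draw_psa_parameters(m, 200), "range-fitted beta")
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("identical seeds reproduce the sample set exactly", {
  m <- default_model()
  a <- run_psa(m, "overall", n = 25, seed = 123)
  b <- run_psa(m, "overall", n = 25, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$costs, b$costs)
  expect_identical(a$ceac, b$ceac)
  expect_equal(nrow(a$draws), 25)
  expect_equal(nrow(a$scatter), 25)
})

test_that("acceptability probabilities sum to one at every threshold", {
  m <- default_model()
  p <- run_psa(m, "esr1", n = 40, seed = 7,
               wtp_grid = seq(0, 300000, by = 50000))
  sums <- as.vector(tapply(p$ceac$probability, p$ceac$wtp, sum))
  expect_equal(sums, rep(1, length(sums)))
  expect_true(all(p$ceac$probability >= 0 & p$ceac$probability <= 1))
})

test_that("an always-dominant strategy has acceptability one everywhere", {
  costs <- cbind(A = rep(10, 50), B = 20 + runif(50))
  qalys <- cbind(A = 2 + runif(50), B = rep(1, 50))
  cc <- ceac_from_draws(costs, qalys, seq(0, 100000, by = 20000), favor = "B")
  expect_true(all(cc$probability[cc$strategy == "A"] == 1))
})

test_that("acceptability of the costlier-but-better arm rises with the threshold", {
  set.seed(31)
  n <- 200
  costs <- cbind(A = 1000 + rnorm(n, sd = 50), B = rep(0, n))
  qalys <- cbind(A = 1 + abs(rnorm(n, 0.5, 0.1)), B = rep(1, n))
  wtp <- seq(0, 5000, by = 250)
  cc <- ceac_from_draws(costs, qalys, wtp, favor = "B")
  pa <- cc$probability[cc$strategy == "A"]
  # brute-force check on the sampled pairs: each draw's acceptance
  # threshold is incr_cost/incr_qalys, so acceptance counts accumulate
  expect_true(all(diff(pa) >= 0))
  thr <- (costs[, "A"] - costs[, "B"]) / (qalys[, "A"] - qalys[, "B"])
  expect_equal(pa, vapply(wtp, function(w) mean(thr <= w), numeric(1)),
               tolerance = 1e-12)
})

test_that("PSA means approach the base case as variances shrink", {
  m <- default_model()
  base <- run_cea(m, "overall")$summary
  r <- m$ranges
  bases <- vapply(r$id, function(id) get_parameter(m, id), numeric(1))
  m$ranges$low <- bases - (r$high - r$low) * 0.005
  m$ranges$high <- bases + (r$high - r$low) * 0.005
  p <- run_psa(m, "overall", n = 100, seed = 17,
               wtp_grid = c(0, 150000))
  expect_equal(colMeans(p$costs)[["ELA"]],
               base$total_cost[base$strategy == "ELA"], tolerance = 0.005)
  expect_equal(colMeans(p$qalys)[["ELA"]],
               base$total_qalys[base$strategy == "ELA"], tolerance = 0.005)
})
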
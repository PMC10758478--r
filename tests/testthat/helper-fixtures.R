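# shared fixtures and small assertion helpers

expect_rel <- function(actual, target, tol) {
  expect_lt(abs(actual - target) / abs(target), tol)
}

# a random valid distribution for property sweeps
random_dist <- function() {
  fam <- sample(surv_families(), 1)
  switch(fam,
    weibull     = surv_dist("weibull", shape = runif(1, 0.5, 3), scale = runif(1, 1, 40)),
    loglogistic = surv_dist("loglogistic", shape = runif(1, 0.8, 3), scale = runif(1, 1, 40)),
    lognormal   = surv_dist("lognormal", meanlog = runif(1, 0, 3.5), sdlog = runif(1, 0.3, 1.5)),
    gompertz    = surv_dist("gompertz", shape = runif(1, 0.005, 0.1), rate = runif(1, 0.01, 0.3)),
    gamma       = surv_dist("gamma", shape = runif(1, 0.5, 3), rate = runif(1, 0.02, 0.5)))
}

# model stripped of economics noise: unit utilities, no AEs, no discount
neutral_model <- function() {
  m <- default_model()
  m$utilities$pf <- 1; m$utilities$pd <- 1
  m$ae_risks <- list(ELA = list(), SOC = list(), FUL = list())
  m$config$annual_discount <- 0
  m
}
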
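#' Simulate a digitized Kaplan-Meier curve with its risk table
#'
#' Stands in for curve digitization of published survival figures:
#' event times are drawn from a known parametric distribution,
#' censoring is applied, the Kaplan-Meier estimate is computed, and
#' the step function is sampled on a regular grid with additive
#' truncated digitizer jitter followed by an isotonic repair pass (so
#' the emitted curve is a valid nonincreasing survival curve starting
#' at 1).  The underlying individual-patient data are returned as the
#' hidden truth for recovery tests.
#'
#' Censoring mechanisms: `"admin"` censors every subject still at risk
#' at `rate` months (administrative cutoff); `"uniform"` censors each
#' subject independently with probability `rate` at a time drawn
#' uniformly on (0, event time).
#'
#' @param true_dist A [surv_dist()] generating the event times.
#' @param n_subjects Number of subjects (>= 10).
#' @param censoring List `(mechanism, rate)`; default no censoring
#'   (`rate = 0` uniform).
#' @param grid_step Digitization grid step in months (default 0.25).
#' @param jitter_sd Standard deviation of the digitizer jitter on the
#'   survival axis (default 0).
#' @param seed Optional integer seed.
#' @return List with elements `curve` ([km_curve()]), `risk`
#'   ([risk_table()]) and `ipd` (the true records).
#' @export
simulate_km <- function(true_dist, n_subjects,
                        censoring = list(mechanism = "uniform", rate = 0),
                        grid_step = 0.25, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(true_dist, "surv_dist"), n_subjects >= 10,
            grid_step > 0, jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  tev <- surv_rand(true_dist, n_subjects)
  event <- rep(1L, n_subjects)
  time <- tev
  mech <- match.arg(censoring$mechanism, c("uniform", "admin"))
  if (mech == "uniform" && censoring$rate > 0) {
    cens <- stats::runif(n_subjects) < censoring$rate
    time[cens] <- stats::runif(sum(cens)) * tev[cens]
    event[cens] <- 0L
  } else if (mech == "admin") {
    cutoff <- censoring$rate
    cens <- tev > cutoff
    time[cens] <- cutoff
    event[cens] <- 0L
  }
  ipd <- structure(data.frame(time = time, event = event),
                   class = c("ipd", "data.frame"))
  km <- km_estimate(ipd)
  grid <- seq(0, max(time), by = grid_step)
  if (length(grid) < 2) stop("all subjects censored before the first grid point",
                             call. = FALSE)
  s <- km_surv_at(km, grid)
  if (jitter_sd > 0) {
    s <- s + pmax(pmin(stats::rnorm(length(s), 0, jitter_sd), 3 * jitter_sd),
                  -3 * jitter_sd)
    s <- pmin(pmax(s, 0), 1)
    s <- cummin(s)   # isotonic repair: digitized survival must not increase
  }
  s[1] <- 1
  n_risk <- vapply(grid, function(g) sum(time >= g - 1e-9), integer(1))
  list(curve = km_curve(grid, s),
       risk = risk_table(grid, n_risk),
       ipd = ipd)
}

#' @rdname simulate_km
#' @param sim A list as returned by `simulate_km()`.
#' @param dir Directory to write `curve.csv` and `risk.csv` into (the
#'   same CSV dialects [read_km_curve()] and [read_risk_table()] read).
#' @export
write_km_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(time = sim$curve$time, survival = sim$curve$survival),
                   file.path(dir, "curve.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = sim$risk$time, n_risk = sim$risk$n_risk),
                   file.path(dir, "risk.csv"), row.names = FALSE)
  invisible(dir)
}
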
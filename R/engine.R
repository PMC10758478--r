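#' State occupancy of the three-state partitioned survival model
#'
#' The partitioned survival model derives cohort occupancy directly
#' from the two survival curves: at evaluation time \eqn{u},
#' progression-free \eqn{pf = \min\{S_{PFS}(u), S_{OS}'(u)\}},
#' progressed \eqn{pd = S_{OS}'(u) - pf} and dead \eqn{1 - S_{OS}'(u)},
#' where \eqn{S_{OS}'(u) = \min\{S_{OS}(u), S_{bg}(u)\}} applies the
#' optional constant background-mortality floor.  A PFS curve lying
#' above OS is clipped (with a warning), never an error.  Occupancy is
#' evaluated at cycle starts, or at cycle midpoints when the
#' half-cycle correction is on.
#'
#' @param pfs,os [surv_dist()] progression-free and overall survival
#'   curves.
#' @param cfg A [psm_config()].
#' @return A `psm_trace` data frame with one row per cycle: `cycle`,
#'   `time` (evaluation time, months), `pf`, `pd`, `dead` (summing to
#'   1), `death_incident` (per-cycle increase of `dead`), `discount`
#'   (the discount factor at the evaluation time).
#' @export
compute_occupancy <- function(pfs, os, cfg) {
  stopifnot(inherits(pfs, "surv_dist"), inherits(os, "surv_dist"),
            inherits(cfg, "psm_config"))
  cycles <- seq_len(cfg$n_cycles)
  offset <- if (cfg$half_cycle) 0.5 else 0
  u <- (cycles - 1 + offset) * cfg$cycle_length
  s_os <- surv_prob(os, u)
  if (cfg$background_annual_mortality > 0) {
    s_bg <- (1 - cfg$background_annual_mortality)^(u / 12)
    s_os <- pmin(s_os, s_bg)
  }
  s_pfs <- surv_prob(pfs, u)
  if (any(s_pfs > s_os + 1e-9)) {
    warning("PFS curve exceeds OS curve at some cycles; clipping PFS to OS",
            call. = FALSE)
  }
  pf <- pmin(s_pfs, s_os)
  pd <- s_os - pf
  dead <- 1 - s_os
  structure(data.frame(
    cycle = cycles, time = u, pf = pf, pd = pd, dead = dead,
    death_incident = c(dead[1], diff(dead)),
    discount = (1 + cfg$annual_discount)^(-u / 12)),
    class = c("psm_trace", "data.frame"))
}

#' Accumulate discounted costs, QALYs and life-years along a trace
#'
#' Per cycle, the cost increment is
#' `pf * (drug-if-on-treatment + follow-up) + pd * (after-progression +
#' subsequent-treatment + drug-if-until-death) + incident-death *
#' end-of-life`, plus the expected adverse-event cost in cycle 1; the
#' QALY increment is `(pf * u_PF + pd * u_PD) * cycle/12` minus the
#' cycle-1 adverse-event disutility; the life-year increment is
#' `(pf + pd) * cycle/12`.  Every increment is multiplied by the
#' discount factor at its evaluation time.
#'
#' @param trace A `psm_trace` from [compute_occupancy()].
#' @param model A `cea_model`.
#' @param strategy Strategy name.
#' @return A list: `strategy`, `total_cost` (USD), `total_qalys`,
#'   `total_lys` (years), plus the per-cycle `trace` augmented with
#'   discounted `cost` and `qaly` increment columns.
#' @export
accumulate_economics <- function(trace, model, strategy) {
  cfg <- model$config
  yrs <- cfg$cycle_length / 12
  # dosing schedules distinguish only cycle 1 (loading) from steady state
  drug <- c(drug_cost_per_cycle(model, strategy, 1),
            rep(drug_cost_per_cycle(model, strategy, 2), nrow(trace) - 1L))
  pd_drug <- if (cfg$treatment_duration == "until_death") drug else 0
  cost <- trace$pf * (drug + model$costs$follow_up) +
          trace$pd * (model$costs$after_progression + model$costs$subsequent + pd_drug) +
          trace$death_incident * model$costs$end_of_life
  cost[1] <- cost[1] + ae_first_cycle_cost(model, strategy)
  qaly <- (trace$pf * model$utilities$pf + trace$pd * model$utilities$pd) * yrs
  qaly[1] <- qaly[1] - ae_first_cycle_disutility(model, strategy)
  lys <- (trace$pf + trace$pd) * yrs
  trace$cost <- cost * trace$discount
  trace$qaly <- qaly * trace$discount
  trace$ly <- lys * trace$discount
  list(strategy = strategy,
       total_cost = sum(trace$cost),
       total_qalys = sum(trace$qaly),
       total_lys = sum(trace$ly),
       trace = trace)
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param incr_cost,incr_qalys Incremental cost (USD) and QALYs.
#' @return A list with `icer` (USD/QALY, or `NA` when undefined) and
#'   `note` (`"ok"`, `"dominant"` = cheaper and more effective,
#'   `"dominated"` = costlier and less effective, or
#'   `"undefined (zero QALY difference)"`).
#' @export
icer <- function(incr_cost, incr_qalys) {
  if (incr_qalys == 0) {
    return(list(icer = NA_real_, note = "undefined (zero QALY difference)"))
  }
  if (incr_qalys > 0 && incr_cost <= 0) {
    return(list(icer = incr_cost / incr_qalys, note = "dominant"))
  }
  if (incr_qalys < 0 && incr_cost >= 0) {
    return(list(icer = NA_real_, note = "dominated"))
  }
  list(icer = incr_cost / incr_qalys, note = "ok")
}

#' Run the full cost-effectiveness analysis for one population
#'
#' Builds the occupancy trace for every strategy from the population's
#' PFS/OS curves, accumulates discounted totals, and forms the
#' incremental comparison between the intervention and comparator
#' (default: the population's headline pairing in
#' `model$comparisons`).
#'
#' @param model A `cea_model`.
#' @param population Population key in `model$survival` (`"overall"`
#'   or `"esr1"` in the bundled model).
#' @param strategies Strategies to evaluate (default: all with curves
#'   for this population).
#' @param comparison Length-2 character vector
#'   `c(intervention, comparator)`.
#' @return A `cea_result`: per-strategy data frame `summary` (columns
#'   `strategy`, `total_cost`, `total_qalys`, `total_lys`), the
#'   incremental block `incremental` (`incr_cost`, `incr_qalys`,
#'   `incr_lys`, `icer`, `note`), and the per-strategy `traces`.
#' @export
run_cea <- function(model, population = "overall", strategies = NULL,
                    comparison = NULL) {
  surv <- model$survival[[population]]
  if (is.null(surv)) stop("unknown population: ", population, call. = FALSE)
  if (is.null(strategies)) {
    strategies <- intersect(names(model$strategies), names(surv$pfs))
  }
  if (length(strategies) < 2) stop("need at least 2 strategies", call. = FALSE)
  if (is.null(comparison)) comparison <- model$comparisons[[population]]
  stopifnot(all(comparison %in% strategies))

  results <- lapply(strategies, function(s) {
    trace <- compute_occupancy(surv$pfs[[s]], surv$os[[s]], model$config)
    accumulate_economics(trace, model, s)
  })
  names(results) <- strategies
  summary <- data.frame(
    strategy = strategies,
    total_cost = vapply(results, `[[`, numeric(1), "total_cost"),
    total_qalys = vapply(results, `[[`, numeric(1), "total_qalys"),
    total_lys = vapply(results, `[[`, numeric(1), "total_lys"),
    row.names = NULL)
  a <- results[[comparison[1]]]; b <- results[[comparison[2]]]
  ic <- a$total_cost - b$total_cost
  iq <- a$total_qalys - b$total_qalys
  ratio <- icer(ic, iq)
  structure(list(
    population = population,
    summary = summary,
    incremental = data.frame(
      intervention = comparison[1], comparator = comparison[2],
      incr_cost = ic, incr_qalys = iq,
      incr_lys = a$total_lys - b$total_lys,
      icer = ratio$icer, note = ratio$note),
    traces = lapply(results, `[[`, "trace")),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> population: %s\n", x$population))
  s <- x$summary
  s$total_cost <- sprintf("%.0f", s$total_cost)
  s$total_qalys <- sprintf("%.3f", s$total_qalys)
  s$total_lys <- sprintf("%.3f", s$total_lys)
  print(s, row.names = FALSE)
  i <- x$incremental
  cat(sprintf("  %s vs %s: incr cost %.0f, incr QALYs %.4f, ICER %s (%s)\n",
              i$intervention, i$comparator, i$incr_cost, i$incr_qalys,
              ifelse(is.na(i$icer), "NA", sprintf("%.0f", i$icer)), i$note))
  invisible(x)
}
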
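#' Per-cycle drug acquisition (and administration) cost of a strategy
#'
#' Mixture-weighted sum over a strategy's drug components.  Oral drugs
#' are charged `mg_per_day x days_per_cycle / unit_size x unit_cost`.
#' Intramuscular fulvestrant is charged per 500 mg administration; its
#' loading schedule puts two administrations (days 1 and 15) in model
#' cycle 1 and one in every later cycle, and each injection-bearing
#' administration also carries the administration fee.
#'
#' @param model A `cea_model`.
#' @param strategy Strategy name in `model$strategies`.
#' @param cycle Cycle index (1-based).
#' @return USD per cycle (drug acquisition plus injection
#'   administration fees), before state occupancy weighting.
#' @examples
#' m <- default_model()
#' drug_cost_per_cycle(m, "ELA", 1)   # 2.175 * 400 * 30 = 26100
#' @export
drug_cost_per_cycle <- function(model, strategy, cycle) {
  stopifnot(cycle >= 1)
  spec <- model$strategies[[strategy]]
  if (is.null(spec)) stop("unknown strategy: ", strategy, call. = FALSE)
  total <- 0
  for (cmp in spec$components) {
    drug <- model$drugs[[cmp$drug]]
    if (is.null(drug)) stop("unknown drug: ", cmp$drug, call. = FALSE)
    if (identical(drug$route, "oral")) {
      per_cycle <- drug$mg_per_day * model$config$days_per_cycle /
        drug$unit_size * drug$unit_cost
    } else if (identical(drug$route, "intramuscular")) {
      admins <- if (cycle == 1) drug$cycle1_admins else drug$steady_admins
      per_cycle <- admins * (drug$mg_per_admin / drug$unit_size * drug$unit_cost +
                             model$costs$administration)
    } else {
      stop("unknown route for drug ", cmp$drug, call. = FALSE)
    }
    total <- total + cmp$weight * per_cycle
  }
  total
}

#' First-cycle adverse-event cost and disutility
#'
#' Grade 3/4 adverse events are applied once, in the first model
#' cycle: expected cost is \eqn{\sum_j risk_j \times cost_j} and the
#' QALY decrement is \eqn{\sum_j risk_j \times d_j \times (cycle/12)}
#' where \eqn{d_j} is the annual disutility.
#'
#' @param model A `cea_model`.
#' @param strategy Strategy name (its `ae_profile` selects the risk set).
#' @return `ae_first_cycle_cost`: USD; `ae_first_cycle_disutility`:
#'   QALYs (a nonnegative decrement).
#' @export
ae_first_cycle_cost <- function(model, strategy) {
  risks <- model$ae_risks[[model$strategies[[strategy]]$ae_profile]]
  if (is.null(risks) || length(risks) == 0) return(0)
  sum(vapply(names(risks), function(ev) {
    risks[[ev]] * model$costs$ae[[ev]]
  }, numeric(1)))
}

#' @rdname ae_first_cycle_cost
#' @export
ae_first_cycle_disutility <- function(model, strategy) {
  risks <- model$ae_risks[[model$strategies[[strategy]]$ae_profile]]
  if (is.null(risks) || length(risks) == 0) return(0)
  sum(vapply(names(risks), function(ev) {
    risks[[ev]] * model$disutilities[[ev]]
  }, numeric(1))) * model$config$cycle_length / 12
}
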
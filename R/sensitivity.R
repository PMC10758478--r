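#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter in `specs` is set to its low and then its high bound
#' with all other parameters at base value, the full cost-effectiveness
#' analysis is re-run, and the incremental cost-effectiveness ratio of
#' the population's headline comparison is recorded.  Entries are
#' returned sorted by spread (|ICER at high - ICER at low|),
#' descending — the tornado ordering.
#'
#' @param model A `cea_model`.
#' @param population Population key.
#' @param specs Data frame with columns `id`, `low`, `high` (default:
#'   the model's bundled ranges).
#' @return A `tornado` data frame: `id`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `spread`, plus the base-case ICER as attribute
#'   `base_icer`.
#' @export
one_way_dsa <- function(model, population = "overall", specs = model$ranges) {
  base <- run_cea(model, population)$incremental$icer
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    id <- specs$id[i]
    get_parameter(model, id)  # errors on unknown ids before any run
    at <- function(v) {
      run_cea(set_parameter(model, id, v), population)$incremental$icer
    }
    lo <- at(specs$low[i]); hi <- at(specs$high[i])
    data.frame(id = id, low = specs$low[i], high = specs$high[i],
               icer_at_low = lo, icer_at_high = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base
  class(out) <- c("tornado", "data.frame")
  out
}

#' Tornado diagram
#'
#' @param x A `tornado` from [one_way_dsa()].
#' @param n_top How many parameters to show (default 12).
#' @param ... Unused.
#' @export
plot.tornado <- function(x, n_top = 12, ...) {
  d <- utils::head(x, n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  rng <- range(c(d$icer_at_low, d$icer_at_high, base))
  graphics::par(mar = c(5, 12, 2, 1))
  graphics::plot(NULL, xlim = rng, ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "ICER (USD/QALY)", ylab = "",
                 main = "One-way sensitivity analysis")
  for (i in seq_len(nrow(d))) {
    graphics::segments(d$icer_at_low[i], i, d$icer_at_high[i], i, lwd = 8,
                       col = "steelblue")
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$id, las = 1, cex.axis = 0.7)
  invisible(x)
}

# moment-matched second-order distributions: gamma for costs, beta for
# probabilities/utilities; sd = (high - low) / (2 * 1.96) treats the
# printed range as a 95% interval
psa_sd <- function(low, high) (high - low) / (2 * 1.96)

draw_one <- function(kind, base, low, high, n) {
  s <- psa_sd(low, high)
  if (s == 0 || base == 0) return(rep(base, n))
  if (kind == "cost") {
    shape <- (base / s)^2
    stats::rgamma(n, shape = shape, rate = shape / base)
  } else if (kind %in% c("prob", "utility")) {
    v <- s^2
    if (v < base * (1 - base)) {
      a <- base * (base * (1 - base) / v - 1)
      b <- (1 - base) * (base * (1 - base) / v - 1)
      stats::rbeta(n, a, b)
    } else {
      # infeasible moment match: fall back to a beta rescaled onto the
      # printed range
      warning(sprintf(
        "beta moment match infeasible (base %.4g, sd %.4g); using range-fitted beta",
        base, s), call. = FALSE)
      low + (high - low) * stats::rbeta(n, 2, 2)
    }
  } else {
    rep(base, n)  # rates (discount) are not varied probabilistically
  }
}

#' Draw parameter vectors for probabilistic sensitivity analysis
#'
#' Costs are drawn from gamma and probabilities/utilities from beta
#' distributions, moment-matched so the mean equals the base value and
#' the standard deviation is (high - low)/(2 x 1.96); draws are clipped
#' to valid domains by construction.  The discount rate is held fixed.
#' Set `utility_dist = "normal"` to reproduce the alternative normal
#' specification for utilities (clipped to \[0, 1\]).
#'
#' @param model A `cea_model`.
#' @param n Number of draws.
#' @param utility_dist `"beta"` (default) or `"normal"`.
#' @return An `n` x p matrix of draws, columns named by parameter id.
#'   Call [set.seed()] (or use [run_psa()]'s `seed`) for
#'   reproducibility.
#' @export
draw_psa_parameters <- function(model, n, utility_dist = c("beta", "normal")) {
  utility_dist <- match.arg(utility_dist)
  specs <- model$ranges
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    base <- get_parameter(model, specs$id[i])
    kind <- specs$kind[i]
    if (kind == "utility" && utility_dist == "normal") {
      pmin(pmax(stats::rnorm(n, base, psa_sd(specs$low[i], specs$high[i])), 0), 1)
    } else {
      draw_one(kind, base, specs$low[i], specs$high[i], n)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- specs$id
  m
}

#' Probabilistic sensitivity analysis
#'
#' Seeded second-order Monte Carlo: for each of `n` parameter draws the
#' full cost-effectiveness analysis is re-evaluated; the result holds
#' the per-draw (cost, QALY) pairs per strategy, the incremental
#' scatter for the headline comparison, and the cost-effectiveness
#' acceptability curve — for each willingness-to-pay value, the
#' fraction of draws in which each strategy has the highest net
#' monetary benefit (NMB = WTP x QALYs - cost; ties are awarded to the
#' comparator, once).
#'
#' @param model A `cea_model`.
#' @param population Population key.
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed; identical seeds give identical sample
#'   sets.
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default 0 to
#'   500,000 by 10,000).
#' @param utility_dist Passed to [draw_psa_parameters()].
#' @return A `psa_result`: `draws` (parameter matrix), `costs` and
#'   `qalys` (n x strategy matrices), `scatter` (incremental pairs),
#'   `ceac` (long data frame wtp x strategy x probability),
#'   `prob_ce_at_wtp` (probability the intervention is cost-effective
#'   at `model$wtp`), `seed`, `n`.
#' @export
run_psa <- function(model, population = "overall", n = 1000, seed = 1,
                    wtp_grid = seq(0, 500000, by = 10000),
                    utility_dist = c("beta", "normal")) {
  utility_dist <- match.arg(utility_dist)
  set.seed(seed)
  draws <- draw_psa_parameters(model, n, utility_dist)
  comparison <- model$comparisons[[population]]
  strategies <- intersect(names(model$strategies),
                          names(model$survival[[population]]$pfs))
  costs <- qalys <- matrix(NA_real_, n, length(strategies),
                           dimnames = list(NULL, strategies))
  for (i in seq_len(n)) {
    mi <- model
    for (id in colnames(draws)) mi <- set_parameter(mi, id, draws[i, id])
    res <- run_cea(mi, population, strategies, comparison)
    costs[i, ] <- res$summary$total_cost
    qalys[i, ] <- res$summary$total_qalys
  }
  scatter <- data.frame(
    incr_qalys = qalys[, comparison[1]] - qalys[, comparison[2]],
    incr_cost = costs[, comparison[1]] - costs[, comparison[2]])
  ceac <- ceac_from_draws(costs, qalys, wtp_grid, favor = comparison[2])
  p_ce <- ceac$probability[ceac$strategy == comparison[1] &
                           ceac$wtp == model$wtp]
  if (!length(p_ce)) {  # model WTP not on the grid: evaluate it directly
    at_wtp <- ceac_from_draws(costs, qalys, model$wtp, favor = comparison[2])
    p_ce <- at_wtp$probability[at_wtp$strategy == comparison[1]]
  }
  structure(list(draws = draws, costs = costs, qalys = qalys,
                 scatter = scatter, ceac = ceac,
                 comparison = comparison, population = population,
                 prob_ce_at_wtp = p_ce, wtp = model$wtp,
                 seed = seed, n = n),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve from PSA draws
#'
#' @param costs,qalys n x strategy matrices of per-draw totals.
#' @param wtp_grid Willingness-to-pay values.
#' @param favor Strategy awarded ties (the comparator).
#' @return Long data frame `wtp`, `strategy`, `probability`; per WTP
#'   the probabilities sum to 1.
#' @export
ceac_from_draws <- function(costs, qalys, wtp_grid, favor = colnames(costs)[1]) {
  strategies <- colnames(costs)
  tie_rank <- ifelse(strategies == favor, 0L, seq_along(strategies))
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qalys - costs
    winner <- apply(nmb, 1, function(r) strategies[order(-r, tie_rank)[1]])
    data.frame(wtp = w, strategy = strategies,
               probability = vapply(strategies,
                                    function(s) mean(winner == s), numeric(1)),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s, %d iterations (seed %d)\n",
              x$population, x$n, x$seed))
  cat(sprintf("  P(%s cost-effective vs %s at WTP %s/QALY) = %.3f\n",
              x$comparison[1], x$comparison[2],
              format(x$wtp, big.mark = ","), x$prob_ce_at_wtp))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  wide <- stats::reshape(x$ceac, idvar = "wtp", timevar = "strategy",
                         direction = "wide")
  graphics::matplot(wide$wtp, as.matrix(wide[, -1]), type = "l", lty = 1,
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1),
                    main = "Cost-effectiveness acceptability curves")
  graphics::legend("right", legend = sub("^probability\\.", "", names(wide)[-1]),
                   col = seq_len(ncol(wide) - 1), lty = 1, bty = "n")
  invisible(x)
}
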
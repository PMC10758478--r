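#' Run the base case and write a reproducible report
#'
#' Evaluates the cost-effectiveness analysis for one population and
#' writes the results table (per-strategy totals, incrementals, ICER),
#' the per-strategy cycle traces, a copy of the configuration, and a
#' run manifest (config checksum, seed, population, evaluation modes,
#' package version) into `out_dir`.  Runs with identical manifests are
#' byte-identical except for the manifest's timestamp field.
#'
#' @param model A `cea_model`.
#' @param population Population key.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer recorded in the manifest (the base case itself
#'   is deterministic).
#' @return The `cea_result`, invisibly; files are written as a side
#'   effect.
#' @export
run_base_case <- function(model, population = "overall", out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_cea(model, population)
  cfg_path <- file.path(out_dir, "config.json")
  write_model_config(model, cfg_path)
  utils::write.csv(cea_table(res), file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  for (s in names(res$traces)) {
    utils::write.csv(res$traces[[s]],
                     file.path(out_dir, sprintf("trace_%s.csv", s)),
                     row.names = FALSE)
  }
  manifest <- list(
    config = "config.json",
    config_checksum = unname(tools::md5sum(cfg_path)),
    seed = seed,
    population = population,
    modes = list(half_cycle = model$config$half_cycle,
                 days_per_cycle = model$config$days_per_cycle,
                 treatment_duration = model$config$treatment_duration),
    tool_version = as.character(utils::packageVersion("psmcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Flatten a `cea_result` into a base-case results table
#'
#' One row per strategy with totals; the intervention row carries the
#' incremental columns and ICER of the headline comparison.
#'
#' @param res A `cea_result`.
#' @return Data frame with columns `strategy`, `total_cost`,
#'   `total_qalys`, `total_lys`, `incr_cost`, `incr_qalys`, `icer`,
#'   `note`.
#' @export
cea_table <- function(res) {
  s <- res$summary
  s$incr_cost <- NA_real_; s$incr_qalys <- NA_real_
  s$icer <- NA_real_; s$note <- ""
  i <- match(res$incremental$intervention, s$strategy)
  s$incr_cost[i] <- res$incremental$incr_cost
  s$incr_qalys[i] <- res$incremental$incr_qalys
  s$icer[i] <- res$incremental$icer
  s$note[i] <- paste0("vs ", res$incremental$comparator, ": ",
                      res$incremental$note)
  s
}

#' Evaluation-convention grid
#'
#' Re-runs the base case under every combination of the evaluation
#' conventions the source model's GUI origin leaves undocumented:
#' half-cycle correction on/off, 30 vs 30.4375 dosing days per cycle,
#' and drug continuation until progression vs until death.  Used to
#' choose (and then freeze) the convention that best reproduces the
#' published base case.
#'
#' @param model A `cea_model`.
#' @param populations Populations to evaluate.
#' @return Data frame: one row per convention x population with the
#'   intervention/comparator totals and ICER.
#' @export
convention_grid <- function(model, populations = names(model$survival)) {
  grid <- expand.grid(half_cycle = c(FALSE, TRUE),
                      days_per_cycle = c(30, 30.4375),
                      treatment_duration = c("until_progression", "until_death"),
                      population = populations,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- model
    m$config$half_cycle <- grid$half_cycle[i]
    m$config$days_per_cycle <- grid$days_per_cycle[i]
    m$config$treatment_duration <- grid$treatment_duration[i]
    res <- run_cea(m, grid$population[i])
    comp <- res$incremental
    s <- res$summary
    iv <- s[s$strategy == comp$intervention, ]
    cp <- s[s$strategy == comp$comparator, ]
    cbind(grid[i, ], data.frame(
      intervention = comp$intervention, comparator = comp$comparator,
      cost_int = iv$total_cost, qalys_int = iv$total_qalys,
      lys_int = iv$total_lys,
      cost_comp = cp$total_cost, qalys_comp = cp$total_qalys,
      lys_comp = cp$total_lys,
      incr_cost = comp$incr_cost, incr_qalys = comp$incr_qalys,
      icer = comp$icer))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-vs-data diagnostic medians
#'
#' The published model medians and the analytic medians of the fitted
#' parameters need not agree (the former may come from reconstructed
#' Kaplan-Meier data).  This diagnostic surfaces both: the analytic
#' median of each configured survival distribution, so an analyst can
#' compare against trial-reported medians without the package forcing
#' agreement.
#'
#' @param model A `cea_model`.
#' @return Data frame `population`, `endpoint`, `strategy`, `family`,
#'   `analytic_median` (months).
#' @export
median_diagnostics <- function(model) {
  rows <- list()
  for (pop in names(model$survival)) {
    for (ep in names(model$survival[[pop]])) {
      for (arm in names(model$survival[[pop]][[ep]])) {
        d <- model$survival[[pop]][[ep]][[arm]]
        rows[[length(rows) + 1L]] <- data.frame(
          population = pop, endpoint = ep, strategy = arm,
          family = d$family, analytic_median = surv_median(d))
      }
    }
  }
  do.call(rbind, rows)
}
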
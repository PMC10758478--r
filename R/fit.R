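#' Maximum-likelihood fitting of parametric survival models
#'
#' Fits one of the five extrapolation families to right-censored
#' individual-patient data by maximizing
#' \deqn{\ell = \sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i),}
#' with parameters transformed to an unconstrained scale (log for
#' positive parameters) and three optimizer starts to guard against the
#' flat likelihoods of the Gompertz and gamma families.
#'
#' @param ipd Data frame with `time` and `event` columns (>= 2 events).
#' @param family One of [surv_families()].
#' @return A `surv_fit` object: list with elements `dist` (the fitted
#'   [surv_dist()]), `loglik`, `aic` (\eqn{2k - 2\ell}), `bic`
#'   (\eqn{k\log n - 2\ell}), `n`, `k`, `converged`.
#' @export
fit_distribution <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  time <- pmax(ipd$time, 1e-6)  # density at exactly 0 is degenerate
  event <- ipd$event
  if (sum(event) < 2) stop("need at least 2 events to fit", call. = FALSE)
  n <- length(time)

  negll <- function(theta) {
    d <- theta_to_dist(theta, family)
    ll <- sum(log(pmax(surv_dens(d, time[event == 1]), 1e-300))) +
          sum(log(pmax(surv_prob(d, time[event == 0]), 1e-300)))
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  for (theta0 in fit_starts(time, event, family)) {
    opt <- try(stats::optim(theta0, negll, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed for family ", family,
                          call. = FALSE)
  converged <- best$convergence == 0
  if (!converged) {
    warning("optimizer did not converge for family ", family, call. = FALSE)
  }
  k <- 2L
  loglik <- -best$value
  structure(list(dist = theta_to_dist(best$par, family),
                 loglik = loglik,
                 aic = 2 * k - 2 * loglik,
                 bic = k * log(n) - 2 * loglik,
                 n = n, k = k, converged = converged),
            class = "surv_fit")
}

theta_to_dist <- function(theta, family) {
  switch(family,
    weibull     = surv_dist("weibull", shape = exp(theta[1]), scale = exp(theta[2])),
    loglogistic = surv_dist("loglogistic", shape = exp(theta[1]), scale = exp(theta[2])),
    lognormal   = surv_dist("lognormal", meanlog = theta[1], sdlog = exp(theta[2])),
    gompertz    = surv_dist("gompertz", shape = theta[1], rate = exp(theta[2])),
    gamma       = surv_dist("gamma", shape = exp(theta[1]), rate = exp(theta[2])))
}

# moment-based start plus two perturbations (multi-start)
fit_starts <- function(time, event, family) {
  tev <- time[event == 1]
  m <- mean(tev); s <- stats::sd(tev); if (!is.finite(s) || s == 0) s <- m / 2
  lm <- mean(log(tev)); ls <- stats::sd(log(tev)); if (!is.finite(ls) || ls == 0) ls <- 0.5
  base <- switch(family,
    weibull     = c(0, log(m)),
    loglogistic = c(log(1.5), log(stats::median(tev))),
    lognormal   = c(lm, log(ls)),
    gompertz    = c(0.01, log(1 / m)),
    gamma       = c(log(max((m / s)^2, 0.1)), log(max(m / s^2, 1e-3))))
  list(base, base + c(0.4, 0.4), base - c(0.4, 0.4))
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s  loglik = %.3f  AIC = %.3f  BIC = %.3f  (n = %d%s)\n",
              x$dist$family, x$loglik, x$aic, x$bic, x$n,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$dist)
  invisible(x)
}

#' Fit all five families and tabulate goodness of fit
#'
#' @param ipd Data frame with `time` and `event` columns.
#' @param families Families to fit (default all five).
#' @return Named list of `surv_fit` objects.
#' @export
fit_all_families <- function(ipd, families = surv_families()) {
  fits <- lapply(families, function(f) fit_distribution(ipd, f))
  names(fits) <- families
  fits
}

#' Select the best-fitting family by information criteria
#'
#' Returns the minimum-AIC fit; ties are broken by BIC, then by the
#' fixed family order of [surv_families()].  The AIC/BIC table that
#' supports the analyst's visual check is available via
#' [fit_table()] and the overlay plot via [plot_fit_overlay()] — the
#' visual judgment itself is deliberately left to a human.
#'
#' @param fits Nonempty list of `surv_fit` objects.
#' @return The selected `surv_fit`.
#' @export
select_best <- function(fits) {
  stopifnot(length(fits) >= 1)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged fits to select from", call. = FALSE)
  if (!all(ok)) warning("excluding non-converged fits from selection", call. = FALSE)
  fits <- fits[ok]
  fam_rank <- match(vapply(fits, function(f) f$dist$family, character(1)),
                    surv_families())
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  fits[[order(aic, bic, fam_rank)[1]]]
}

#' @rdname select_best
#' @export
fit_table <- function(fits) {
  data.frame(
    family = vapply(fits, function(f) f$dist$family, character(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    row.names = NULL)
}

#' @rdname select_best
#' @param path CSV destination for the AIC/BIC table.
#' @export
write_fit_table <- function(fits, path) {
  utils::write.csv(fit_table(fits), path, row.names = FALSE)
  invisible(path)
}

#' Overlay fitted curves on the Kaplan-Meier estimate
#'
#' Supports the visual goodness-of-fit check: plots the KM step
#' function of the data with each fitted parametric curve on top.
#'
#' @param ipd Data frame with `time` and `event`.
#' @param fits List of `surv_fit` objects.
#' @param horizon Plot range in months (default 1.2 x max time).
#' @export
plot_fit_overlay <- function(ipd, fits, horizon = NULL) {
  km <- km_estimate(ipd)
  if (is.null(horizon)) horizon <- 1.2 * max(ipd$time)
  graphics::plot(km$time, km$survival, type = "s", xlim = c(0, horizon),
                 ylim = c(0, 1), xlab = "Months", ylab = "Survival",
                 main = "Parametric fits vs Kaplan-Meier")
  tt <- seq(0, horizon, length.out = 200)
  for (j in seq_along(fits)) {
    graphics::lines(tt, surv_prob(fits[[j]]$dist, tt), col = j + 1)
  }
  graphics::legend("topright",
                   legend = vapply(fits, function(f) f$dist$family, character(1)),
                   col = seq_along(fits) + 1, lty = 1, bty = "n")
  invisible(NULL)
}
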
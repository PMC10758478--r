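#' Parametric survival distributions for extrapolation
#'
#' Construct one of the five parametric survival families used to
#' extrapolate progression-free and overall survival beyond trial
#' follow-up.  Time is always measured in months.
#'
#' The parameterization conventions are part of the public contract:
#' \describe{
#'   \item{weibull}{`shape` \eqn{a > 0}, `scale` \eqn{b > 0};
#'     \eqn{S(t) = \exp\{-(t/b)^a\}} (the accelerated-failure-time form
#'     used by [stats::pweibull()]).}
#'   \item{loglogistic}{`shape` \eqn{a > 0}, `scale` \eqn{b > 0};
#'     \eqn{S(t) = 1 / (1 + (t/b)^a)}; the median equals `scale`.}
#'   \item{lognormal}{`meanlog` \eqn{\mu}, `sdlog` \eqn{\sigma > 0};
#'     \eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)}; the median equals
#'     \eqn{e^\mu}.}
#'   \item{gompertz}{`shape` \eqn{a} (any real), `rate` \eqn{b > 0};
#'     \eqn{S(t) = \exp\{-(b/a)(e^{at} - 1)\}}, reducing to the
#'     exponential with rate \eqn{b} as \eqn{a \to 0}.  Negative shapes
#'     give a defective distribution (a surviving fraction), which is
#'     permitted for extrapolation.}
#'   \item{gamma}{`shape` \eqn{a > 0}, `rate` \eqn{b > 0};
#'     \eqn{S(t) = 1 - F_{\Gamma}(t; a, b)} per [stats::pgamma()].}
#' }
#'
#' @param family One of `"weibull"`, `"loglogistic"`, `"lognormal"`,
#'   `"gompertz"`, `"gamma"`.
#' @param ... Named parameters for the family (see Details), e.g.
#'   `surv_dist("lognormal", meanlog = 1.41, sdlog = 0.96)`.
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("lognormal", meanlog = 1.414933, sdlog = 0.958343)
#' surv_prob(d, c(0, 6, 12))
#' surv_median(d)
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, surv_families())
  params <- c(...)
  if (is.list(params)) params <- unlist(params)
  expected <- surv_param_names(family)
  if (!setequal(names(params), expected)) {
    stop(sprintf("family '%s' requires parameters {%s}, got {%s}",
                 family, paste(expected, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- params[expected]
  if (any(!is.finite(params))) {
    stop("distribution parameters must be finite", call. = FALSE)
  }
  # domain checks: every parameter strictly positive except lognormal
  # meanlog and gompertz shape, which may be any real
  free <- switch(family, lognormal = "meanlog", gompertz = "shape", character(0))
  pos <- setdiff(expected, free)
  if (any(params[pos] <= 0)) {
    stop(sprintf("parameters {%s} must be > 0 for family '%s'",
                 paste(pos, collapse = ", "), family), call. = FALSE)
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_dist")
}

#' @rdname surv_dist
#' @export
surv_families <- function() {
  c("weibull", "loglogistic", "lognormal", "gompertz", "gamma")
}

surv_param_names <- function(family) {
  switch(family,
         weibull     = c("shape", "scale"),
         loglogistic = c("shape", "scale"),
         lognormal   = c("meanlog", "sdlog"),
         gompertz    = c("shape", "rate"),
         gamma       = c("shape", "rate"),
         stop("unknown family: ", family, call. = FALSE))
}

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("<surv_dist> %s(%s), time in %s\n", x$family,
              paste(sprintf("%s = %g", names(x$params), x$params),
                    collapse = ", "),
              x$time_unit))
  invisible(x)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  t
}

#' Survival, density and hazard functions
#'
#' `surv_prob()` evaluates \eqn{S(t)}, `surv_dens()` the density
#' \eqn{f(t)} and `surv_haz()` the hazard \eqn{h(t) = f(t)/S(t)} of a
#' [surv_dist()] at times `t` (months).
#'
#' @param dist A `surv_dist`.
#' @param t Vector of nonnegative times in months.
#' @return Numeric vector the length of `t`; `surv_prob()` is in
#'   \[0, 1\] with \eqn{S(0) = 1}.
#' @export
surv_prob <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  t <- check_time(t)
  p <- dist$params
  s <- switch(dist$family,
    weibull     = stats::pweibull(t, p["shape"], p["scale"], lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p["scale"])^p["shape"]),
    lognormal   = stats::plnorm(t, p["meanlog"], p["sdlog"], lower.tail = FALSE),
    gompertz    = surv_gompertz(t, p["shape"], p["rate"]),
    gamma       = stats::pgamma(t, p["shape"], rate = p["rate"], lower.tail = FALSE))
  s[t == 0] <- 1
  unname(pmin(pmax(s, 0), 1))
}

# S(t) = exp(-(rate/shape) (e^{shape t} - 1)); expm1 keeps the shape -> 0
# limit (exponential) numerically exact
surv_gompertz <- function(t, shape, rate) {
  if (abs(shape) < 1e-12) return(exp(-rate * t))
  exp(-(rate / shape) * expm1(shape * t))
}

#' @rdname surv_prob
#' @export
surv_dens <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  t <- check_time(t)
  p <- dist$params
  d <- switch(dist$family,
    weibull     = stats::dweibull(t, p["shape"], p["scale"]),
    loglogistic = {
      a <- p["shape"]; b <- p["scale"]
      (a / b) * (t / b)^(a - 1) / (1 + (t / b)^a)^2
    },
    lognormal   = stats::dlnorm(t, p["meanlog"], p["sdlog"]),
    gompertz    = p["rate"] * exp(p["shape"] * t) * surv_gompertz(t, p["shape"], p["rate"]),
    gamma       = stats::dgamma(t, p["shape"], rate = p["rate"]))
  unname(d)
}

#' @rdname surv_prob
#' @export
surv_haz <- function(dist, t) {
  surv_dens(dist, t) / pmax(surv_prob(dist, t), .Machine$double.xmin)
}

#' Median survival time
#'
#' Closed forms are used where available (log-normal \eqn{e^\mu},
#' log-logistic `scale`, Weibull \eqn{b (\log 2)^{1/a}}, gamma quantile,
#' Gompertz inversion); otherwise the root of \eqn{S(t) - 1/2} is
#' bracketed and bisected.  A defective Gompertz whose surviving
#' fraction exceeds one half has no median and returns `Inf`.
#'
#' @param dist A `surv_dist`.
#' @return Median time in months.
#' @export
surv_median <- function(dist) {
  p <- dist$params
  m <- switch(dist$family,
    weibull     = unname(p["scale"] * log(2)^(1 / p["shape"])),
    loglogistic = unname(p["scale"]),
    lognormal   = unname(exp(p["meanlog"])),
    gamma       = stats::qgamma(0.5, p["shape"], rate = p["rate"]),
    gompertz    = {
      a <- p["shape"]; b <- p["rate"]
      if (abs(a) < 1e-12) log(2) / b
      else {
        arg <- 1 + a * log(2) / b
        if (arg <= 0) Inf else log(arg) / a   # defective: no median
      }
    })
  unname(m)
}

#' Restricted mean survival time
#'
#' The area under \eqn{S(t)} from 0 to `horizon` months, by adaptive
#' quadrature.  Always finite and bounded above by `horizon`, even for
#' families whose unrestricted mean diverges.
#'
#' @param dist A `surv_dist`.
#' @param horizon Positive upper limit in months.
#' @return Restricted mean in months.
#' @export
surv_rmst <- function(dist, horizon) {
  stopifnot(is.numeric(horizon), length(horizon) == 1, horizon > 0)
  val <- stats::integrate(function(u) surv_prob(dist, u), 0, horizon,
                          rel.tol = 1e-9, subdivisions = 500L)$value
  min(val, horizon)
}

#' Random event times from a parametric survival distribution
#'
#' Inversion sampling via \eqn{S^{-1}(U)}; used by the synthetic
#' Kaplan-Meier generator.  A defective Gompertz returns `Inf` for
#' draws landing in the surviving fraction.
#'
#' @param dist A `surv_dist`.
#' @param n Number of draws.
#' @return Vector of `n` event times in months.
#' @export
surv_rand <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    weibull     = stats::rweibull(n, p["shape"], p["scale"]),
    lognormal   = stats::rlnorm(n, p["meanlog"], p["sdlog"]),
    gamma       = stats::rgamma(n, p["shape"], rate = p["rate"]),
    loglogistic = {
      u <- stats::runif(n)
      p[["scale"]] * (u / (1 - u))^(1 / p[["shape"]])
    },
    gompertz    = {
      u <- stats::runif(n)
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) -log(u) / b
      else {
        arg <- 1 - (a / b) * log(u)
        ifelse(arg > 0, log(arg) / a, Inf)
      }
    })
}
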
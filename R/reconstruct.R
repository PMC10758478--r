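#' Digitized Kaplan-Meier curves and number-at-risk tables
#'
#' `km_curve()` holds the ordered (time, survival) coordinates read off
#' a published Kaplan-Meier plot; `risk_table()` holds the
#' number-at-risk row printed beneath it.  Both are validated: times
#' must increase, survival and at-risk counts must not increase, and
#' the curve is normalized to start at (0, 1).
#'
#' @param time Times in months (curve: strictly increasing from 0;
#'   risk table: increasing interval start times).
#' @param survival Survival probabilities in \[0, 1\], nonincreasing.
#' @param n_risk Nonnegative, nonincreasing integer counts; the first
#'   entry is the number enrolled.
#' @return A `km_curve` / `risk_table` data frame.
#' @seealso [reconstruct_ipd()], [read_km_curve()]
#' @export
km_curve <- function(time, survival) {
  stopifnot(length(time) == length(survival), length(time) >= 1)
  if (time[1] > 0) {  # normalize: a curve always starts at (0, 1)
    time <- c(0, time); survival <- c(1, survival)
  }
  if (any(diff(time) <= 0)) stop("curve times must be strictly increasing", call. = FALSE)
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]", call. = FALSE)
  if (any(diff(survival) > 1e-9)) stop("survival must be nonincreasing", call. = FALSE)
  survival <- cummin(pmin(survival, 1))
  survival[1] <- 1
  structure(data.frame(time = time, survival = survival),
            class = c("km_curve", "data.frame"))
}

#' @rdname km_curve
#' @export
risk_table <- function(time, n_risk) {
  stopifnot(length(time) == length(n_risk), length(time) >= 1)
  if (any(diff(time) <= 0)) stop("risk-table times must be increasing", call. = FALSE)
  if (any(n_risk < 0) || any(diff(n_risk) > 0)) {
    stop("n_risk must be nonnegative and nonincreasing", call. = FALSE)
  }
  structure(data.frame(time = time, n_risk = as.integer(round(n_risk))),
            class = c("risk_table", "data.frame"))
}

#' @rdname km_curve
#' @param path CSV file with headers `time,survival` (curve) or
#'   `time,n_risk` (risk table).
#' @export
read_km_curve <- function(path) {
  d <- utils::read.csv(path)
  km_curve(d$time, d$survival)
}

#' @rdname km_curve
#' @export
read_risk_table <- function(path) {
  d <- utils::read.csv(path)
  risk_table(d$time, d$n_risk)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Inverts the Kaplan-Meier estimator: given digitized curve
#' coordinates and the number-at-risk table, recovers a set of event
#' and censoring times whose Kaplan-Meier estimate steps through the
#' digitized coordinates, following the iterative interval algorithm of
#' Guyot and colleagues.  Censoring within each at-risk interval is
#' spread uniformly (the algorithm's canonical choice).  Patients still
#' at risk past the last digitized time are censored there.
#'
#' @param curve A [km_curve()].
#' @param risk A [risk_table()] covering the curve's time range; its
#'   first entry is the number enrolled (must be >= 2).
#' @return An `ipd` data frame with columns `time` (months) and `event`
#'   (1 = event, 0 = censored), one row per reconstructed patient; row
#'   count equals the initial number at risk.
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ (2012).
#'   Enhanced secondary analysis of survival data: reconstructing the
#'   data from published Kaplan-Meier survival curves.
#'   BMC Med Res Methodol 12:9.
#' @export
reconstruct_ipd <- function(curve, risk) {
  stopifnot(inherits(curve, "km_curve"), inherits(risk, "risk_table"))
  t.S <- curve$time; S <- curve$survival
  t.risk <- risk$time; n.risk <- risk$n_risk
  K <- length(t.S); nint <- length(t.risk)
  if (n.risk[1] < 2) stop("initial number at risk must be >= 2", call. = FALSE)
  if (any(n.risk == 0) && min(which(n.risk == 0)) < nint) {
    stop("risk table drops to zero before the curve ends", call. = FALSE)
  }
  if (t.risk[1] > t.S[1]) stop("risk table must start at or before the curve", call. = FALSE)

  # map risk intervals onto coordinate indices
  lower <- upper <- integer(nint)
  bounds <- c(t.risk, Inf)
  for (i in seq_len(nint)) {
    in.i <- which(t.S >= bounds[i] & t.S < bounds[i + 1])
    lower[i] <- if (length(in.i)) min(in.i) else NA_integer_
    upper[i] <- if (length(in.i)) max(in.i) else NA_integer_
  }

  d <- integer(K)          # events at each coordinate
  cens_times <- numeric(0) # censoring times (within intervals)
  n.hat <- numeric(K + 1); n.hat[1] <- n.risk[1]
  KM.hat <- numeric(K); KM.hat[1] <- 1
  last <- 1L               # index of last coordinate with an event

  for (i in seq_len(nint)) {
    if (is.na(lower[i])) next
    lo <- lower[i]; up <- upper[i]
    has_next <- i < nint && !is.na(lower[i + 1])
    if (has_next) {
      # initial guess of censorings from the no-censoring projection
      proj <- n.hat[lo] * S[lower[i + 1]] / max(KM.hat[last], 1e-12)
      n.cens <- round(proj) - n.risk[i + 1]
      n.cens <- max(n.cens, 0L)
    } else {
      n.cens <- 0L
    }
    t.end <- if (has_next) t.S[lower[i + 1]] else t.S[up]

    repeat {
      # spread the guessed censorings uniformly across the interval
      ct <- if (n.cens > 0) {
        t.S[lo] + seq_len(n.cens) * (t.end - t.S[lo]) / (n.cens + 1)
      } else numeric(0)
      nh <- n.hat; km <- KM.hat; dd <- d; lst <- last
      nh[lo] <- n.hat[lo]
      for (k in lo:up) {
        if (k == 1L) {
          dd[k] <- 0L; km[k] <- 1
        } else {
          dd[k] <- round(nh[k] * (1 - S[k] / max(km[lst], 1e-12)))
          dd[k] <- max(min(dd[k], nh[k]), 0L)
          km[k] <- km[lst] * (1 - dd[k] / max(nh[k], 1e-12))
        }
        ck <- sum(ct >= t.S[k] &
                    ct < (if (k < K) t.S[k + 1] else Inf))
        nh[k + 1] <- nh[k] - dd[k] - ck
        if (dd[k] > 0) lst <- k
      }
      if (!has_next) {
        n.hat <- nh; KM.hat <- km; d <- dd; last <- lst
        cens_times <- c(cens_times, ct)
        break
      }
      delta <- nh[lower[i + 1]] - n.risk[i + 1]
      if (delta == 0 || (n.cens == 0 && delta < 0)) {
        n.hat <- nh; KM.hat <- km; d <- dd; last <- lst
        cens_times <- c(cens_times, ct)
        break
      }
      n.cens <- max(n.cens + delta, 0L)
    }
  }

  ev_times <- rep(t.S, d)
  n_left <- n.risk[1] - length(ev_times) - length(cens_times)
  if (n_left < 0) stop("reconstruction produced more records than enrolled", call. = FALSE)
  tail_cens <- rep(t.S[K], n_left)  # administratively censored at curve end
  out <- data.frame(
    time = c(ev_times, cens_times, tail_cens),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cens_times) + n_left)))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ipd", "data.frame"))
}

#' Kaplan-Meier estimate of reconstructed (or simulated) patient data
#'
#' Thin wrapper around [survival::survfit()] returning the step
#' function as a data frame aligned with [km_curve()].
#'
#' @param ipd Data frame with `time` and `event` columns.
#' @return Data frame with columns `time` and `survival` (the KM step
#'   values immediately after each event time), starting at (0, 1).
#' @export
km_estimate <- function(ipd) {
  fit <- survival::survfit(survival::Surv(ipd$time, ipd$event) ~ 1,
                           conf.type = "none")
  data.frame(time = c(0, fit$time), survival = c(1, fit$surv))
}

#' @rdname km_estimate
#' @param km A data frame with `time` and `survival` (a KM step
#'   function as returned by `km_estimate()`).
#' @param t Times at which to evaluate the right-continuous step
#'   function.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    k <- which(km$time <= ti + 1e-12)
    if (length(k)) km$survival[max(k)] else 1
  }, numeric(1))
}
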
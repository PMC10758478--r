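---
title: "Partitioned survival cost-effectiveness modelling with psmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned survival cost-effectiveness modelling with psmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The model

`psmcea` implements a three-state partitioned survival model (PSM) for
oncology cost-effectiveness analysis. A cohort starts progression-free
(PF); the proportions in the three mutually exclusive states —
progression-free, progressed disease (PD), dead — are read directly off
two survival curves rather than derived from transition probabilities:

* progression-free: $pf(u) = \min\{S_{PFS}(u),\, S_{OS}'(u)\}$
* progressed: $pd(u) = S_{OS}'(u) - pf(u)$
* dead: $1 - S_{OS}'(u)$

where $S_{OS}'(u) = \min\{S_{OS}(u), S_{bg}(u)\}$ applies an optional
constant-hazard background-mortality floor $S_{bg}$ (off by default:
disease-specific OS for this population sits far below general-population
survival over a 10-year horizon, so a realistic floor never binds). The
defining assumption of a PSM — and its main limitation — is that the two
curves are independent marginals: there is no structural link between
progression and death, so a PFS curve crossing above OS is a modelling
artifact, which the engine clips (never errors) and reports.

The bundled model (`default_model()`) compares three strategies for
second/third-line endocrine therapy of HR+/HER2− advanced breast
cancer: an oral SERD (elacestrant, ELA), the standard-of-care mixture
(SOC: 69.33% fulvestrant, 10.22% each anastrozole/letrozole/exemestane),
and fulvestrant monotherapy (FUL). The headline comparisons are ELA vs
SOC in the overall population and ELA vs FUL in the ESR1-mutation
subgroup.

## Survival extrapolation

Five parametric families are supported, with the parameterization an
explicit part of the contract (`?surv_dist`): Weibull and gamma in the
`stats` conventions, log-normal with $S(t) = 1 - \Phi((\log t - \mu)/\sigma)$,
log-logistic with $S(t) = 1/(1 + (t/b)^a)$ (median $= b$), and Gompertz
$S(t) = \exp\{-(b/a)(e^{at}-1)\}$, computed through `expm1` so the
$a \to 0$ exponential limit is numerically exact. Time is always in
months. All curve parameters in the bundled model are treated as given
inputs — they were estimated upstream from reconstructed trial data that
are not public, so the package cannot (and does not try to) re-derive
them.

One diagnostic deserves emphasis: the analytic medians of the bundled
curves (`median_diagnostics()`) do **not** match the medians reported
alongside them in the source material (e.g. the overall-population ELA
PFS log-normal has analytic median $e^{1.414933} = 4.12$ months where
3.37 is reported). The reported values are plausibly medians of the
reconstructed Kaplan–Meier data rather than of the fitted curves. The
package deliberately surfaces both numbers and forces no agreement.

## Curve reconstruction and fitting

When digitized curve coordinates and a number-at-risk table are
available, `reconstruct_ipd()` rebuilds pseudo individual-patient data
by the iterative interval algorithm of Guyot et al. (2012): within each
at-risk interval the number of censorings is guessed from the
no-censoring projection, spread **uniformly** across the interval (the
algorithm's canonical choice; nothing finer is identifiable from a
digitized figure), events are back-calculated from the KM steps, and the
guess is adjusted until the implied at-risk count matches the printed
one. At-risk counts follow the standard plotting convention: the number
printed at time $t$ counts subjects still under observation *just
before* $t$.

`fit_distribution()` maximizes the right-censored log-likelihood
$\sum_{d_i=1}\log f(t_i) + \sum_{d_i=0}\log S(t_i)$ with parameters
mapped to an unconstrained scale (log transforms for positive
parameters; the Gompertz shape stays free and may go negative, giving a
defective distribution) and a 3-start Nelder–Mead search, because the
Gompertz and gamma likelihoods can be flat. Non-convergence is warned
about and flagged, never silently replaced. `select_best()` takes the
minimum-AIC fit (ties: BIC, then fixed family order); the "visual
simulation" part of model selection is deliberately left to a human,
supported by `plot_fit_overlay()` and `fit_table()`.

## Economics

All costs are USD from a payer perspective; utilities are annual
weights. Per cycle, costs accrue as

* PF: drug acquisition (+ injection administration fee for
  intramuscular components) + follow-up;
* PD: after-progression care + subsequent treatment (+ drug if
  treatment runs until death — see conventions);
* incident deaths: a one-time end-of-life payment, computed from the
  per-cycle increase of the dead compartment (telescoping to at most one
  payment per patient);
* cycle 1 only: expected grade-3/4 adverse-event cost
  $\sum_j r_j c_j$ and QALY decrement $\sum_j r_j d_j/12$.

QALYs accrue as $(pf \cdot u_{PF} + pd \cdot u_{PD})/12$ per monthly
cycle and life-years as $(pf+pd)/12$; every increment is discounted by
$(1+r)^{-u/12}$ at its evaluation time ($r = 3\%$/year by default,
bounded at 5%). Fulvestrant's loading schedule (500 mg on days 1 and 15
of cycle 1, then monthly) puts two administrations — and two injection
fees — in model cycle 1. Oral dosing is charged for 30 days per cycle by
default, matching 30-tablet pack pricing.

## Evaluation conventions and the frozen setting

The published analysis this model re-implements was built in a GUI tool
whose discretization conventions are not documented, and three of them
materially affect totals: half-cycle evaluation, days of oral dosing per
cycle, and whether drug cost continues into the progressed state. The
package exposes all three as flags (`psm_config()`), whose *generic*
defaults follow the stated assumptions (cycle-start evaluation, 30
days, treatment until progression).

`convention_grid()` re-runs the base case under all eight combinations.
Run against the published base-case table, the grid shows:

* treatment **until death** is the only branch that reaches the
  published cost magnitudes (stopping drug at progression leaves the
  intervention arm at roughly half the published total), even though
  the stated costing assumption is treatment until progression — the
  discrepancy is surfaced, not reconciled;
* within that branch, midpoint (half-cycle) evaluation with 30-day
  cycles tracks the published QALY and life-year totals best.

`default_model(convention = "frozen")` therefore ships with
`half_cycle = TRUE, days_per_cycle = 30, treatment_duration =
"until_death"`, and the run manifest records these modes. One published
anchor remains out of reach under *every* convention: the
overall-population ICER. With the printed OS parameters the
standard-of-care log-normal (sdlog 1.093) has a heavier tail than the
intervention's (sdlog 0.851); the curves cross near month 35, so over a
120-month discounted horizon the comparator accrues *more* life-years,
the QALY increment is ≈0.06 rather than the published ≈0.09, and the
ICER lands ≈40% above the published value — while the incremental cost
agrees to ~1% and the subgroup ICER to ~4%. The published life-year row
itself is inconsistent with its own printed OS parameters on this fine
margin, so the package reports what the stated inputs imply.

## Sensitivity analysis

`one_way_dsa()` sets each parameter to its published low/high bound
(ranges are sorted first — one published range is printed inverted; ±20%
is the stated default where no range is given) with everything else at
base, re-runs the full analysis, and returns tornado entries sorted by
ICER spread. Monotonicity of the ICER in a parameter is *checked by
sweep in the tests*, never assumed.

`run_psa()` is a seeded second-order Monte Carlo: costs are drawn from
gamma and probabilities/utilities from beta distributions,
moment-matched so the mean equals the base value and the SD is
(high − low)/(2 × 1.96) — i.e. the printed range is read as a 95%
interval, since no hyper-parameters are published. The source text
states "normal" and "β" for utilities in adjacent sentences; beta is
adopted (it respects the [0, 1] domain and the cited good-practice
guidance), with `utility_dist = "normal"` retained as a switch. An
infeasible beta moment match (SD too large for the mean) falls back to a
beta rescaled onto the printed range, with a warning. The discount rate
varies in the one-way analysis only, and survival-curve parameters are
varied in neither — no ranges are published for them, a scope limitation
the source itself acknowledges; conclusions about decision uncertainty
therefore condition on the fitted curves.

The CEAC reports, per willingness-to-pay value, the fraction of draws in
which each strategy has the highest net monetary benefit
$\mathrm{NMB} = \lambda \cdot \mathrm{QALY} - \mathrm{cost}$; exact ties
are awarded to the comparator, once, so probabilities sum to 1. The
default grid runs 0–500,000 USD/QALY in steps of 10,000 (unstated
upstream; chosen to bracket the 150,000 threshold comfortably).

## Synthetic data

`simulate_km()` generates what a curve digitizer would produce: event
times drawn from a known family, administrative or uniform censoring,
the exact KM step function sampled on a grid, truncated Gaussian jitter
on the survival axis, and an isotonic repair pass so the emitted curve
is still a valid survival function. It emulates grid resolution and
reading noise; it does **not** emulate pixel-level digitizer artifacts
(axis miscalibration, step-corner ambiguity), so a green
reconstruction test establishes correctness of the inversion, not
robustness to every real-world digitization flaw. Default test scales
(n = 200 for roundtrips, n = 5000 for parameter recovery) mirror
realistic trial-arm sizes and the asymptotic-recovery regime
respectively.

## Numerical choices

* Restricted means use adaptive quadrature (`integrate`, rel.tol 1e-9);
  medians use closed forms where they exist, bisection otherwise.
* Survival evaluations clamp to [0, 1] and pin $S(0) = 1$ exactly.
* Likelihood evaluations floor density/survival at 1e-300 before
  logging; event times at exactly 0 are nudged to 1e-6 months.
* Occupancy conservation ($pf + pd + dead = 1$) holds to 1e-12 by
  construction and is property-tested on 1000 random draws.
* Defective Gompertz curves (negative shape) have no median when the
  surviving fraction exceeds one half; `surv_median()` returns `Inf`.

## Limitations

* The PSM's independent-marginals assumption (no structural PF→PD→death
  link) is inherited, as is the absence of survival-parameter
  uncertainty in the PSA.
* The fulvestrant arm has no published OS curve of its own; it follows
  the pooled standard-of-care OS of the full population in both
  populations — the assignment that reproduces the published
  fulvestrant life-years. A fulvestrant-specific curve would change the
  subgroup comparison.
* The subsequent-therapy mix is priced as a single pooled per-cycle
  charge, and grade-1/2 adverse events are excluded, as upstream.
* The evaluation-convention calibration (previous section) matches
  totals, not mechanism: it cannot distinguish *why* the GUI original
  accrued drug cost past progression.
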
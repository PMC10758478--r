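# psmcea

A tested engine for three-state **partitioned survival
cost-effectiveness analysis** (PSM CEA) in oncology, for health
economists and HTA analysts who need a scriptable, reproducible
alternative to GUI decision-tree tools.

A PSM derives cohort occupancy directly from two survival curves:
progression-free occupancy is the area under PFS, alive is the area
under OS, progressed is their difference, dead is the complement:

    pf(u) = min{S_PFS(u), S_OS(u)},  pd(u) = S_OS(u) − pf(u),
    dead(u) = 1 − S_OS(u)

Discounted costs, QALYs and life-years accumulate per monthly cycle,
and strategies are compared by the incremental cost-effectiveness
ratio ICER = Δcost/ΔQALY against a willingness-to-pay threshold λ via
the net monetary benefit NMB = λ·QALY − cost.

The package covers the full pipeline:

* **Survival curves** — five parametric extrapolation families
  (Weibull, log-logistic, log-normal, Gompertz, gamma) with documented
  parameterizations, closed-form medians, restricted means
  (`surv_dist()`, `surv_prob()`, `surv_median()`, `surv_rmst()`).
* **Curve reconstruction** — pseudo individual-patient data from
  digitized Kaplan–Meier coordinates + number-at-risk tables (the Guyot
  algorithm), maximum-likelihood fitting of all five families with
  AIC/BIC selection (`reconstruct_ipd()`, `fit_distribution()`,
  `select_best()`).
* **The PSM engine** — occupancy traces, discounted accumulation,
  incremental comparison (`compute_occupancy()`, `run_cea()`).
* **Sensitivity analysis** — one-way tornado (`one_way_dsa()`) and
  seeded probabilistic analysis with CEAC (`run_psa()`).
* **Synthetic data** — digitized-curve simulator with censoring and
  digitizer jitter so the whole pipeline is testable offline
  (`simulate_km()`).

It ships a fully parameterised model of second/third-line endocrine
therapy for HR+/HER2− advanced/metastatic breast cancer — oral SERD
elacestrant (ELA) vs the standard-of-care endocrine mixture (SOC) vs
fulvestrant (FUL) — with every input (curve parameters, drug prices and
dosing, state costs, adverse-event risks/costs/disutilities, utilities,
discount rate, sensitivity ranges) in one editable configuration
(`default_model()`, JSON round-trip via `write_model_config()`).

## Worked example

```r
library(psmcea)
m <- default_model()

run_cea(m, "overall")
#> <cea_result> population: overall
#>  strategy total_cost total_qalys total_lys
#>       ELA    1219538       1.358     2.593
#>       SOC     466915       1.296     2.643
#>       FUL     474726       1.296     2.643
#>   ELA vs SOC: incr cost 752623, incr QALYs 0.0618, ICER 12177684 (ok)

run_cea(m, "esr1")
#> <cea_result> population: esr1
#>  strategy total_cost total_qalys total_lys
#>       ELA    1365774       1.580     2.938
#>       SOC     382237       1.079     2.181
#>       FUL     478449       1.286     2.643
#>   ELA vs FUL: incr cost 887325, incr QALYs 0.2932, ICER 3025928 (ok)
```

Reading: over a 10-year horizon at a 3% annual discount, the ELA arm
costs ~$1.22M and yields 1.36 QALYs in the overall population; the
incremental $752,623 buys 0.062 QALYs, an ICER of ~$12.2M/QALY —
far above any accepted US willingness-to-pay threshold ($150,000/QALY
here). In the ESR1-mutation subgroup the ICER vs fulvestrant is
~$3.0M/QALY. Probabilistic analysis confirms the decision is not
uncertainty-sensitive:

```r
run_psa(m, "esr1", n = 1000, seed = 42)
#> <psa_result> esr1, 1000 iterations (seed 42)
#>   P(ELA cost-effective vs FUL at WTP 150,000/QALY) = 0.000

head(data.frame(one_way_dsa(m, "overall")), 3)
#>                       id icer_at_low icer_at_high  spread
#> 1    drugs.ELA.unit_cost     5610503     14805764 9195262
#> 2           utilities.pf    17166051      9435713 7730337
#> 3 config.annual_discount    16387393     10572205 5815188
```

The tornado's dominant driver is the intervention's unit price,
followed by the health-state utilities.

Reconstruction from a digitized curve:

```r
sim <- simulate_km(surv_dist("weibull", shape = 1.3, scale = 8),
                   n_subjects = 200,
                   censoring = list(mechanism = "uniform", rate = 0.2),
                   grid_step = 0.5, seed = 42)
ipd  <- reconstruct_ipd(sim$curve, sim$risk)
best <- select_best(fit_all_families(ipd))
```

## Acceptance script

`scripts/acceptance.R` rebuilds the bundled model from its configuration
and recomputes the headline base-case quantities from scratch — the
ICERs of both population comparisons and the intervention arm's
discounted totals (cost, QALYs, life-years) — writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The evaluation conventions it runs under (half-cycle evaluation, 30-day
dosing cycles, treatment until death) were frozen after a documented
grid search; see the methods vignette
(`vignettes/partitioned-survival-cea.Rmd`) for why, and for one known
structural discrepancy in the overall-population ICER.
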
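Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for Oncology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested engine for three-state partitioned survival
    cost-effectiveness analysis of oncology treatments: closed-form
    parametric survival families (Weibull, log-logistic, log-normal,
    Gompertz, gamma) for extrapolation, reconstruction of pseudo
    individual-patient data from digitized Kaplan-Meier curves with
    number-at-risk tables, maximum-likelihood fitting with AIC/BIC
    selection, discounted cost/QALY/life-year accumulation with
    incremental cost-effectiveness ratios, one-way deterministic
    sensitivity analysis (tornado), and seeded probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves.  Ships a
    fully parameterised model of second-line endocrine therapy for
    HR-positive/HER2-negative advanced breast cancer (oral SERD versus
    standard-of-care endocrine therapy) and a synthetic-data generator
    for digitized survival curves so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
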
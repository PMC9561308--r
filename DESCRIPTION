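Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for Advanced
    Endometrial Cancer Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead)
    partitioned-survival cohort model comparing lenvatinib plus
    pembrolizumab against single-agent chemotherapy for previously
    treated mismatch repair-proficient advanced endometrial cancer,
    from a Chinese payer perspective. Provides parametric survival
    laws (log-logistic and five comparators) with maximum-likelihood
    fitting of right-censored data and AIC/BIC model selection,
    Kaplan-Meier utilities, simulation of pseudo individual patient
    data, emulated curve digitization and curve-to-patient-record
    reconstruction, per-cycle cost and quality-adjusted life-year
    accumulation with discounting, incremental cost-effectiveness
    analysis against a willingness-to-pay threshold, one-way
    deterministic sensitivity analysis with tornado output, and
    seeded probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml,
    jsonlite,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
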
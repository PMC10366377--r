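Package: prscea
Title: Cost-Effectiveness of Polygenic Risk Screening in Workplace
    Cardiovascular Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Annual-cycle Markov cohort model of a 5-year workplace
    cardiovascular prevention program that adds a coronary-artery-disease
    polygenic risk score (CAD-PRS) to pooled-cohort-equation (PCE) risk
    screening. Twenty-two health states capture PCE/PRS risk strata, statin
    side effects (diabetes, hemorrhagic stroke, myopathy), primary outcomes
    (CAD, ischemic stroke), their pairwise comorbidities, and death. The
    package computes discounted costs (medical, lost productivity, program)
    and quality-adjusted life years for three strategies, incremental
    cost-effectiveness and net monetary benefit, one-way and probabilistic
    sensitivity analyses, and a scenario with annual migration across PCE
    risk categories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
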
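Package: pcascreen
Title: Microsimulation Cost-Effectiveness Model of PSA-Based Prostate Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A population microsimulation model for evaluating prostate-specific
    antigen (PSA) screening strategies in an ageing male population. Combines a
    natural-history model of prostate cancer (log-linear PSA growth with an
    onset change-point, and age- and PSA-dependent hazards of tumour onset,
    metastasis and clinical detection), a screening decision tree
    (PSA test, MRI triage, biopsy), an eight-state monthly Markov model of
    post-diagnosis prognosis, and a health-economic layer (discounted costs,
    quality-adjusted life years, incremental cost-effectiveness ratios, net
    monetary benefit and cost-effectiveness acceptability curves). Includes
    deterministic population projection, MCMC calibration of PSA growth
    parameters, a multiplier grid search for hazard calibration, one-way and
    probabilistic sensitivity analysis, risk-stratified (polygenic risk score)
    screening arms, and synthetic-data generators so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
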
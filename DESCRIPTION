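Package: checkup45
Title: Cost-Effectiveness Modelling of the Australian 45-49 Year Old Health Check
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic pipeline for evaluating the Medicare-funded
    45-49 year old health check against usual care in Australian general
    practice. Generates synthetic risk-factor profiles from categorical
    survey-style distributions, translates them into 5-year cardiovascular
    disease risk with the parametric Framingham risk equation, extrapolates
    lifetime outcomes with a 12-state annual-cycle Markov cohort model
    (stable/unstable angina, myocardial infarction, stroke and TIA tunnel and
    post-event states), and computes discounted costs, QALYs, incremental
    cost-effectiveness ratios, deterministic scenario analyses and a full
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
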
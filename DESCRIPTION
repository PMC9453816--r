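Package: nsclcCEA
Title: Markov Cohort Cost-Effectiveness Model for Second-Line Therapy in
    Advanced NSCLC
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cohort state-transition (Markov) model comparing tislelizumab,
    docetaxel and nivolumab as second- or third-line therapy for
    driver-negative advanced or metastatic non-small cell lung cancer from
    the Chinese healthcare system perspective. Log-logistic parametric
    survival curves are turned into per-cycle transition probabilities, a
    four-state cohort trace (with treatment-discontinuation sub-states and
    post-progression tunnel time) is propagated over a 30-year horizon, and
    discounted costs and quality-adjusted life-years feed incremental
    cost-effectiveness ratios, net monetary benefit, one-way deterministic
    sensitivity analysis with tornado ranking, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Includes a
    synthetic individual-patient-data generator and Kaplan-Meier inversion
    utilities so the parametric fitting stage (AIC/BIC model selection over
    five families) is testable without trial data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
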
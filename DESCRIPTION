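Package: statinpolicy
Title: Cost-Effectiveness Modelling of Statin Prioritisation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A decision-analytic pipeline for comparing statin prioritisation
    policies in primary cardiovascular disease prevention: a competing-risk
    multistate cohort simulator with ASSIGN-style risk factors, 10-year risk
    scoring, absolute-risk-reduction (ARR) guided eligibility, strategy
    calibration to matched treated counts, health-economic valuation (QALYs,
    discounted costs), probabilistic sensitivity analysis with correlated
    hazard-ratio draws, and cost-effectiveness synthesis (ICER frontier with
    extended dominance, net monetary benefit, acceptability curves, tornado
    analyses). Ships a synthetic cohort generator emulating the joint
    risk-factor structure of a national health survey, including partial
    missingness and statin detreatment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
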
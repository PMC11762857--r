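Package: statinsim
Title: Microsimulation of Statin Initiation Thresholds for ASCVD Primary
    Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level annual-cycle microsimulation for
    cost-effectiveness analysis of 10-year atherosclerotic cardiovascular
    disease (ASCVD) risk thresholds for starting moderate-intensity statin
    therapy in a Chinese middle-aged and elderly population. Generates
    synthetic baseline cohorts, computes 10-year ASCVD risk from a
    Cox-form risk equation (China-PAR form), converts it to annual event
    probabilities by the declining exponential (DEALE) method, simulates
    coronary heart disease and stroke events, case fatality, statin-induced
    diabetes, treatment discontinuation, and background mortality, accrues
    discounted costs and quality-adjusted life years, ranks strategies on
    the cost-effectiveness frontier with extended dominance, and provides
    one-way deterministic and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
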
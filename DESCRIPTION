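Package: swingbra
Title: Patient-Preference Benefit-Risk Analysis with Adaptive Swing Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-centered benefit-risk analysis of medical
    interventions using an additive multi-criteria value model. Implements
    adaptive swing-weighting (ASW) preference elicitation via a three-step
    bisection ladder, conversion of per-attribute indifference points
    (maximum acceptable increase in risk, maximum acceptable reduction in
    benefit) into attribute weights, threshold analysis (maximum acceptable
    risk / minimum acceptable benefit), and Monte Carlo propagation of
    performance uncertainty and preference heterogeneity. Ships the published
    transcatheter vs surgical aortic valve replacement (TAVR vs SAVR)
    configuration and a synthetic respondent-panel generator so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
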
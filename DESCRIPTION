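Package: crisismort
Title: Small-Area Estimation of Crisis-Attributable Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate district-month death rates and excess death
    tolls in humanitarian crises from retrospective household mortality
    surveys, reconstructed population denominators and routinely collected
    predictor data.  Surveys are re-analysed with household-level Poisson
    models offset by person-time and cluster-robust standard errors;
    candidate quasi-Poisson predictive models are screened and ranked by
    cross-validated Dawid-Sebastiani score; excess mortality under
    counterfactual no-crisis scenarios is estimated with a parametric
    bootstrap on model coefficients.  A synthetic-data generator emulates
    the full input stack (SMART-style surveys, discrepant census sources,
    displacement flows, predictor panels) with known ground truth, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
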
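Package: phenopk
Title: Population Pharmacokinetics of Phenobarbital in Dogs with
    Autoinductive Clearance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of phenobarbital
    in dogs: a one-compartment oral-absorption model whose clearance rises
    over time through an enzyme-turnover autoinduction mechanism, simulation
    of sparse therapeutic-drug-monitoring datasets from virtual canine
    populations, nonlinear mixed-effects estimation by adaptive
    Gauss-Hermite quadrature with stepwise covariate selection, external
    validation metrics, normalized prediction distribution errors and
    visual predictive checks, Bayesian forecasting of individual exposure,
    and Monte Carlo evaluation of dosing regimens against the 15-45 mg/L
    therapeutic window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
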
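Package: curox
Title: Kinetics of Oxidative Curcumin Consumption by AAPH-Generated Radicals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and fits a mass-action kinetic model of the oxidative
    consumption of curcumin and curcumin monoacrylate by free radicals
    generated from thermal decomposition of AAPH
    (2,2'-azobis(2-amidinopropane) dihydrochloride). Provides a stiff ODE
    simulator with a quasi-steady-state radical mode, least-squares
    estimation of second-order consumption rate constants from normalized
    consumption time series, a synthetic-data generator for parameter
    recovery studies, and a bolus versus zero-order controlled-release
    dosing comparison summarized by the area under the radical
    deviation-from-baseline curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
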
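Package: lpaa
Title: Stage-Structured Dynamics of Cannibalistic Flour Beetle Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the discrete-time LPAA (larvae, pupae, newly emerged
    adults, mature adults) map of Tribolium population dynamics and the
    classical three-stage LPA model it extends. Provides the update maps,
    projection matrices and Jacobians, net reproductive number, closed-form
    steady states and invariant-region bounds, primitivity checks,
    local/global stability classification including the delay-equation
    reduction of the mature-adult dynamics, rescaled Lyapunov-exponent and
    bifurcation scans, a one-step-forecast weighted least-squares fitting
    pipeline for biweekly census data with adult-cohort reconstruction, and
    a synthetic census generator emulating a multi-group laboratory
    experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
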
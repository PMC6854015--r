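Package: ascorbpk
Title: Population Pharmacokinetics of High-Dose Intravenous Ascorbate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing plasma pharmacokinetics of pharmacological
    ascorbate given as a constant-rate intravenous infusion, built around a
    two-compartment mammillary disposition model. Provides closed-form
    concentration profiles under zero-order input, a stochastic approximation
    EM (SAEM) estimator for nonlinear mixed-effects models with a censored
    (below-limit-of-quantification) likelihood, non-compartmental analysis
    (AUC, terminal slope, steady-state volume), Monte Carlo prediction bands
    for visual predictive checks, normalized prediction distribution errors,
    and a synthetic crossover-study generator that emulates a two-dose
    canine infusion design so every stage of the pipeline can be exercised
    without access to the original animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
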
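Package: thermokin
Title: Thermal Inactivation Kinetics and Activation Thermodynamics of Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a bank of eight kinetic models (first-order, Weibull,
    distinct isoenzymes, two-fraction, multi-component first-order,
    series-type, nth-order decay, fractional conversion) to residual-activity
    decay curves of heat-treated enzymes, selects the admissible model by
    physical and statistical criteria, and derives kinetic (half-life,
    decimal reduction time, z-value, reliable life, z'-value, log-logistic
    temperature dependence of the Weibull scale) and activation
    thermodynamic (Arrhenius activation energy, Eyring Gibbs energy,
    enthalpy and entropy of deactivation) parameters. Includes a synthetic
    decay-curve generator for simulation studies and a pipeline that runs
    read, fit, select, derive and report as one step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
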
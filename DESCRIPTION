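Package: ternadiff
Title: Ternary Taylor-Dispersion Diffusion and Host-Guest Complexation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing coupled (ternary) mutual diffusion of a drug
    with a complexing carrier measured by the Taylor dispersion method.
    Implements the 1:1 host-guest speciation equilibrium, the reduction of the
    three-species flux equations to a 2x2 mutual diffusion coefficient matrix,
    a Stokes-Einstein estimator for the complex diffusivity, weighted
    least-squares estimation of the association constant from diffusion
    coefficient tables with bootstrap uncertainty, micellar solubilized
    fractions and counter-transport diagnostics, and a virtual Taylor
    dispersion instrument (two-mode dispersion profile simulation, nonlinear
    peak fitting, and assembly of the diffusion matrix from paired
    injections). Ships published diffusion-coefficient tables for
    5-fluorouracil with beta-cyclodextrin and with sodium dodecyl sulfate as
    plain-text fixtures, and a synthetic-data generator emulating the
    instrument so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
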
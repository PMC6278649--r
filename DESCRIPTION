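Package: bzfit
Title: Thermodynamic Modelling and Fitting of Protein-Induced B-Z DNA Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium modelling of the B-Z transition of short DNA duplexes
    induced by Z-DNA-binding proteins (ZBPs) through the sequential four-state
    mechanism B, BP, ZP, ZP2. Provides an exact trigonometric solver (with a
    guaranteed numeric fallback) for the cubic free-protein mass balance of the
    coupled binding equilibria, forward models for the three NMR observables used
    to characterise the transition (imino-proton hydrogen-exchange rates versus
    molar ratio or Z-fraction, and amide chemical-shift perturbations), weighted
    nonlinear least-squares fitting of the equilibrium constants including the
    global multi-probe chemical-shift/Z-fraction fit, a synthetic titration
    generator for parameter-recovery studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lhs,
    withr
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
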
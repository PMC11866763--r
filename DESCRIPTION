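Package: ndcrate
Title: Golden-Rule Rates for Nonadiabatic Transitions Driven by Derivative Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes Fermi golden-rule rates for nonadiabatic transitions between
    two electronic states whose coupling is the nuclear-momentum (derivative
    coupling) operator, for displaced harmonic-oscillator baths. Implements the
    three required bath spectral densities (Franck-Condon, squared derivative
    coupling, and their cross coupling) for parametric Ohmic-plus-delta models,
    discrete normal-mode tables, and Brownian-oscillator broadened modes;
    evaluates the lineshape exponent g(t) and the non-Condon kernels F(t) and
    D(t) by spectral quadrature, closed-form thermal sums, or exact discrete-mode
    summation; and assembles rates, Condon reference rates, and energy-gap scans
    with convergence diagnostics. Includes model-case fixtures, a synthetic
    azulene-like mode set, delimited-text I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
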
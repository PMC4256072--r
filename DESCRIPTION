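Package: gainprop
Title: Gain Scaling and Signal Propagation in Conductance-Based
    Feedforward Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates single-compartment Hodgkin-Huxley-style model
    neurons of the modified Mainen type and layered feedforward networks
    built from them, contrasting gain-scaling (high Na/K conductance
    ratio) with nongain-scaling (low ratio) cell types.  Provides
    linear-nonlinear (spike-triggered average) characterization of fast
    fluctuation coding, noise-modulated frequency-current surfaces, a
    mean-field iterated map for layer-to-layer firing-rate propagation
    with fixed-point and line-attractor diagnosis, Gaussian-channel and
    discrete mutual-information measures of signal transmission, and an
    Abbott-Kepler two-variable reduction with phase-plane and bifurcation
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
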
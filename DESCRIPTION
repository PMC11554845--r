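Package: pulmnet
Title: Multiscale Pulmonary Arterial-Venous Hemodynamics with Uncertainty Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulse-wave propagation in the proximal pulmonary arteries and
    veins with a nonlinear one-dimensional solver coupled, through frequency-domain
    grand admittance matrices, to self-similar structured-tree models of the distal
    arterial and venous microcirculation. Computes haemodynamic and mechanobiological
    quantities of interest (pressure, flow, wall shear stress, cyclic stretch, wave
    intensity) and quantifies parameter uncertainty with Legendre polynomial chaos
    emulators, Sobol' and generalized Sobol' sensitivity indices.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lhs,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
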
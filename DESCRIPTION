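Package: consortsim
Title: Simulation of Cell-Length-Controlled Bacterial Consortia in Microfluidic Traps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates two-strain rod-shaped bacterial consortia growing in open
    monolayer microfluidic traps, where dynamic control of a strain's mean
    division length confers a mechanical fitness advantage. Provides three
    complementary model tiers: an agent-based model of growing, dividing,
    mechanically interacting 2D spherocylinders with quorum-sensing signaling
    and threshold-triggered division-length reduction; an event-driven
    stochastic lattice model in which a rotation probability serves as a proxy
    for cell length; and a reduced fast-slow relaxation-oscillator ODE for the
    consortial strain-fraction oscillator. Analysis tools include the nematic
    order parameter, region-wise ordering, kymographs of order and horizontal
    growth-expansion force, strain-fraction time series, and exponential
    rate-parameter fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
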
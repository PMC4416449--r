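Package: bicnn
Title: Bi-Hemispheric Cerebellar Network Model for Adaptive Motor Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and simulates a bi-hemispheric firing-rate model of the
    cerebellar microcircuit (mossy fibers, granule, Golgi, basket/stellate and
    Purkinje cells) wired in 3D by a nearest-neighbour rule under anatomical
    convergence ratios, with climbing-fiber-gated LTD/LTP plasticity at
    parallel-fiber to Purkinje-cell synapses. The network runs in closed loop
    next to a PD controller on simulated motor plants (a DC motor, a two-wheel
    inverted-pendulum robot, and a planar quadcopter pitch subsystem), and an
    experiment harness sweeps graded granule-cell knockdown across seeded
    initial conditions to quantify learning performance and robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
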
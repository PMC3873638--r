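Package: hetmf
Title: Mean-Field Reductions of Heterogeneous Adapting Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing all-to-all coupled networks of adapting
    two-dimensional integrate-and-fire (Izhikevich-type) neurons with
    heterogeneous parameters. Implements three mean-field reductions of the
    network obtained under different moment-closure assumptions (a homogeneous
    reduction at the mean parameters; a reduction with a parameter-resolved
    firing-rate integral; and a reduction retaining the parameter-conditioned
    adaptation field, integrated by the method of lines), together with a
    ground-truth spiking-network simulator, prediction and inversion of
    steady-state firing-rate distributions, per-neuron parameter recovery,
    bursting-fraction analysis over parameter planes, and simulation-based
    location of Hopf, grazing and saddle-node-of-limit-cycle bifurcations of
    the non-smooth mean-field flows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
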
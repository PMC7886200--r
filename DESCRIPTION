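Package: spikelearn
Title: Target-Based Maximum-Likelihood Learning for Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and supervised training of discrete-time recurrent
    networks of leaky integrate-and-fire neurons (current-based and
    conductance-based synapses). A target spike pattern is induced by randomly
    projecting a desired output signal into the recurrence-free network; the
    recurrent weights are then adapted by a plasticity rule derived from
    maximum likelihood, in a spike-dependent or voltage-dependent form, with
    batch gradient ascent or a fully online per-timestep approximation and
    optional Adam step adaptation. A linear readout decodes the spiking
    activity into the output trajectory. Includes task generators and
    experiment drivers for multidimensional trajectory generation, temporal
    XOR, noise-robustness curves, and learning from few presentations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
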
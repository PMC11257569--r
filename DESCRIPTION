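Package: spikeTempo
Title: Temporal Resolution of Spike Coding in Convergent and Divergent
    Feedforward Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how structural
    convergence and divergence in feedforward spiking neural networks shape
    the temporal resolution of population spike codes. Provides synthetic
    time-dependent stimuli, alpha and leaky integrate-and-fire neuron
    simulations with sparse signed connectivity, surrogate-gradient
    backpropagation-through-time training against a dual spike-count and
    spike-timing readout, sliding-window spike binning, recurrent (LSTM/GRU)
    and ridge sequence decoders with Bayesian hyperparameter selection,
    Kraskov-Stogbauer-Grassberger mutual information estimation, a
    single-neuron spike-count versus spike-timing information decomposition,
    closed-form maximum-entropy bounds for count and timing codes, and
    orchestration of multi-seed network experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
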
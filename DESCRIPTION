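Package: semnet
Title: Spiking Cortical Attractor Network Model of Episodic Memory
    Semantization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation of a two-network (item and context)
    cortical attractor memory built from adaptive exponential
    integrate-and-fire neurons with conductance-based AMPA, NMDA and GABA
    synapses and Tsodyks-Markram short-term plasticity.  Associative
    projections between the networks learn with either a spike-based
    Bayesian-Hebbian rule (BCPNN; exponentially averaged Z and P traces
    yielding log-odds weights and log-prior intrinsic excitability) or a
    multiplicative nearest-neighbour STDP rule.  Includes the episodic
    item-context encoding and cued-recall task, an attractor-activation
    detector based on exponential moving averages of population firing
    rates, a postsynaptic-potential measurement harness, a reduced
    seven-neuron microcircuit with continuous weight tracking, and
    utilities to study semantization (item-context decoupling under
    context variability), preferential retention under plasticity
    modulation, and multi-cue recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
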
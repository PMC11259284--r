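Package: plastnet
Title: Spiking Neuronal Networks with Synaptic Weight and Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for excitatory networks of conductance-based leaky
    integrate-and-fire neurons whose synaptic weights evolve by additive
    spike-timing-dependent plasticity (STDP) and whose connectivity evolves by
    a stochastic structural-plasticity birth-death process with homeostatic
    and weight-dependent pruning. Provides the adiabatic multi-timescale
    orchestration of spiking, weight, and structural dynamics, uncorrelated
    multichannel random stimulation (UMRS) with charge-balanced pulses, a
    leak-conductance calibration procedure for controlled firing-rate
    heterogeneity, and a suite of dynamical and structural network measures
    (Kuramoto order parameter, firing-rate statistics, node degree densities,
    directed degree assortativity, contact-lifetime statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
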
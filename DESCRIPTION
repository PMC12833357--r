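Package: thalnet
Title: Conductance-Based Thalamocortical Network Simulation of Spindle and
    Spike-Wave Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a 475-cell single-compartment Hodgkin-Huxley
    thalamocortical network (layer 5 regular-spiking and intrinsically
    bursting pyramidal cells, layer 6 pyramidal cells, deep low-threshold
    spiking interneurons, thalamocortical relay and thalamic reticular
    cells) coupled by two-state kinetic AMPA, GABA-A and GABA-B synapses.
    Provides cortical GABA-A disinhibition (GABRG2-type mutation scaling),
    an allopregnanolone synaptic transform, frontocortical connectivity
    enhancement, point-source local field potentials, Welch band-power
    analysis, and classification of network states into spindle
    oscillations versus spike-wave discharges.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
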
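Package: eiclust
Title: Simulation and Analysis of Excitatory-Inhibitory Clustered Spiking Attractor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates balanced spiking networks of leaky
    integrate-and-fire neurons with exponential synaptic currents, including
    random balanced, excitatory-clustered and jointly excitatory/inhibitory-
    clustered (E/I-clustered) topologies that exhibit metastable attractor
    dynamics and winnerless competition. Provides first-principles calibration
    of synaptic weights for the balanced state from postsynaptic-potential
    amplitudes, spike-train variability statistics (Fano factor, CV, CV2,
    synchrony, time-resolved sliding-window estimators), synthetic spike-train
    generators (Poisson, gamma-renewal, two-state rate switching), a delayed
    center-out reach task protocol with graded prior target information, a
    leaky-integrator decision decoder with threshold crossings and reaction
    times, and cross-validated population decoding of movement direction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    glmnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
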
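Package: microflow
Title: Leaky Integrate-and-Fire Cortical Microcircuit Simulation and
    Directed Phase-Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a conductance-based leaky integrate-and-fire
    microcircuit of visual cortex layers 2/3 composed of excitatory
    pyramidal neurons and three inhibitory interneuron subtypes (PV, SOM,
    VIP), with log-normally distributed excitatory-to-excitatory synaptic
    weights, Poisson background and feedforward drive, and a fast
    compiled Runge-Kutta integrator. Provides the downstream analysis
    stack for studying excitatory/inhibitory (E/I) balance disruptions:
    peristimulus time histograms, trial-averaged power spectra,
    cross-condition band normalization, aperiodic-removed oscillatory
    peak strengths, and Hilbert-phase directed phase lag index (dPLI) and
    phase lag index (PLI) information-flow metrics, together with an
    experiment driver that sweeps E/I ratios by converting PV or SOM
    interneurons into pyramidal neurons at configurable network scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    signal,
    minpack.lm,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
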
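Package: achnet
Title: Spatially Heterogeneous Cholinergic Modulation of E-I Network Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates two-dimensional excitatory-inhibitory networks of
    Hodgkin-Huxley neurons in which acetylcholine signaling is modeled as a
    spatially heterogeneous reduction of the M-type (muscarine-sensitive)
    potassium conductance gKs. Provides generators for diffusion-based gKs
    "hotspot" maps, a fast fixed-step network integrator with conductance
    synapses, and an analysis suite for network and single-cell rhythms:
    correlogram-based power spectra, theta/gamma band classification,
    spike-derived local field potentials, and entropy-based modulation-index
    estimates of theta-gamma phase-amplitude coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
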
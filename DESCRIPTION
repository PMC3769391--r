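Package: hyperbrain
Title: Single-Trial Phase-Coupling Measures and Hyper-Brain Network Analysis for Dual-EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for EEG hyperscanning analysis: single-trial instantaneous
    phase-synchronization measures (PSI, PCI, NCI, ACI and the directed
    integrative coupling index ICI) computed from complex Morlet wavelet
    phases, surrogate-data significance thresholding, and graph-theoretic
    characterization of the resulting two-person ("hyper-brain") networks,
    including strengths with intra-/inter-brain decomposition, clustering,
    path length, small-worldness coefficients sigma and omega against
    degree-matched random and lattice null models, modularity optimization
    for weighted and directed graphs, and Z-P node-role classification.
    Includes a coupled-oscillator synthetic-data generator, readers and
    writers for BrainVision, EDF and delimited recordings, a preprocessing
    chain (re-referencing, band-pass, EOG regression, resampling, epoching,
    artifact rejection, montage selection) and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
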
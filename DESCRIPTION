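Package: cortilam
Title: Layer-Specific Cortical Microstructure and Function Analysis
Version: 0.1.0
Authors@R: person("Cortical", "Layers Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for laminar analysis of the human primary somatosensory
    cortex and mouse barrel cortex: equivolume cortical depth construction and
    data-driven three-compartment segmentation of 21-depth quantitative T1
    profiles, automated low-myelin border (septum) detection along geodesic
    paths on triangulated cortical surface patches, phase-encoded BOLD Fourier
    amplitude and calibrated depth-response profiles, one-dimensional
    population receptive field fitting with a Spearman-Brown noise ceiling,
    eigenvector centrality on rectified correlations, adaptive-staircase and
    signal-detection psychophysics, two-photon calcium trace quantification,
    permutation Welch tests and robust Theil-Sen regression, plus synthetic
    cortical phantom generators that make the full pipeline testable without
    raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
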
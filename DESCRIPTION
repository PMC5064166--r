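Package: ecgibench
Title: Benchmarking Regularized ECG Imaging During Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and benchmarking framework for the inverse problem of
    electrocardiography (ECGI) under fibrillatory conditions. Generates
    kinematic epicardial activity phantoms (sinus rhythm, simple and complex
    atrial fibrillation with a spiral-wave rotor and fibrotic dropout) on
    triangulated atrial surfaces, projects them to body-surface potentials
    through a transfer matrix with Wilson-Central-Terminal referencing, noise
    injection and Butterworth filtering, reconstructs epicardial potentials
    with fourteen regularization methods (Tikhonov orders 0-2 with
    instantaneous or global L-curve parameters, TSVD orders 0-2, DSVD, total
    variation, Bayesian MAP, Greensite spatio-temporal whitening, GMRES), and
    scores the clinical targets (dominant frequency, phase maps, phase
    singularity location) with a metric suite including the spatial mass
    function of singularity location and its weighted under/over-estimation
    indicators, correlation and geodesic mode distance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    optparse
Config/testthat/edition: 3
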
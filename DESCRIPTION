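Package: extrudr
Title: Vertex-Model Simulation and Quantification of Epithelial Cell Extrusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate the early phase of apoptotic cell extrusion in a
    2D epithelial vertex model (Metropolis Monte-Carlo vertex dynamics, T1
    neighbour exchanges, contractility-driven and resting-area-driven
    constriction protocols) and to quantify per-cell fluorescence and shape
    time series: onset (inflection-point) detection by two-segment linear
    fits, pulse detection with topographic prominence, contraction yield,
    normalised cross-correlation, radial averaged kymographs, apicobasal
    profiles, extrusion-duration and cell-elimination statistics. A
    synthetic-data module generates traces, pulsatile myosin/perimeter pairs,
    ring-image stacks and cohorts with known ground truth so every stage of
    the pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    tools,
    utils,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
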
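Package: tvfcstates
Title: Simplicial and Topological State Spaces for Time-Varying
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing instantaneous brain states derived from
    time-varying functional connectivity (TVFC). Parcellated BOLD-like
    time series are decomposed with a complex Morlet continuous wavelet
    transform; smoothed wavelet squared coherence is averaged across
    scales with cross-wavelet power weights to yield per-time-point
    coherence-distance graphs. Instantaneous graphs are compared under
    six metrics: Euclidean distance between node topographies, weighted
    Jaccard distances between edge weights and degree strengths, and
    sliced-Wasserstein distances between Vietoris-Rips persistence
    diagrams in homological dimensions 0 to 2. Metric spaces are embedded
    in two dimensions, segmented with a density watershed transform, and
    assessed with permutation and bootstrap statistics for volunteer
    generalizability, stimulus segmentation, and task-performance
    separation. A synthetic block-design study generator supports
    calibration and null testing without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
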
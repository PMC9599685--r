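Package: aimnet
Title: Event-Locked EEG Functional Connectivity and Brain Network Analysis
    for Marksmanship Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses event-locked multichannel EEG recorded
    while marksmen prepare a shot. Provides a synthetic cohort generator
    with known ground-truth phase-lagged coupling, individual alpha
    frequency (IAF), artifacts and planted performance correlations;
    preprocessing (zero-phase FIR band-pass filtering, event-locked
    epoching, amplitude-based artifact rejection, IAF-anchored band
    division); trial-resolved weighted phase lag index (WPLI) connectivity
    with event-related baseline normalisation (ERWPLI); weighted,
    unthresholded graph metrics (clustering, characteristic path length,
    global and local efficiency, eigenvector centrality); and the
    nonparametric group workflow (Kolmogorov-Smirnov screening, Wilcoxon
    rank-sum contrasts, Spearman performance correlations,
    Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    signal,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
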
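Package: foldscape
Title: Energy-Landscape Analysis of Repeat-Protein Folding Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse coarse-grained folding ensembles of repeat
    proteins on their energy landscape. Implements internal-distance
    structural similarity (q / Q_w) and smoothed fraction-of-native-contacts
    (Q_o) reaction coordinates with per-residue and per-repeat local variants,
    dissimilarity-based low-dimensional projection of conformational
    ensembles by stress majorization (an ELViM-style visualisation),
    umbrella-sampling free-energy profiles combined with the weighted
    histogram analysis method (WHAM), melting-curve folding-temperature
    estimation, and route-level analyses: residue-resolved folding heatmaps,
    apparent-backtracking detection, projection-region contact maps, folding
    route assignment, commitment probabilities and terminal-repeat fraying.
    Includes a synthetic-data suite: toy repeat-protein natives, ground-truth
    parallel-route ensembles, and a minimal C-alpha structure-based (Go-like)
    overdamped Langevin simulator with optional umbrella bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    bio3d,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mgcv,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
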
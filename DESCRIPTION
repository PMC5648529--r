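Package: mnpaths
Title: Comparing Motor-Neuron Differentiation Trajectories from Single-Cell UMI Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for asking whether two motor-neuron
    differentiation protocols (growth-factor-guided and transcription-factor
    direct programming) traverse different intermediate states yet converge on
    the same terminal motor-neuron state. Starting from droplet UMI count
    matrices it performs quality filtering (minimum-UMI threshold, total-count
    normalization, stressed-cell removal), highly-variable and principal-variable
    gene selection with a permutation null on PCA eigenvalues, tSNE embedding and
    density clustering with marker-criteria annotation, Welch t-test differential
    expression with FDR control and transcription-factor filter presets,
    kNN-graph trajectory comparison (centroid cosine similarity, multinomial
    maximum-likelihood cell assignment, kNN label transfer, reference
    neighbor fractions), gene-panel proliferation and cell-cycle-exit scores,
    and an analytic lifetime bound for a hypothetical rare transitional
    subpopulation. A seeded synthetic-data generator emulates two-protocol
    droplet experiments so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    FNN,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
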
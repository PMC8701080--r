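Package: subcloneRDA
Title: Robust Deep Autoencoder Denoising of Single-Cell SNV Genotype
    Matrices and Subclonal Tree Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers clean genotype matrices from noisy, partially observed
    single-cell SNV mutation calls by decomposing the observed matrix into a
    low-rank part (reconstructed through a deep autoencoder) and a sparse
    error part, with the l1 sparsity penalty restricted to observed entries so
    that missing entries are imputed through the low-rank structure. Cells are
    clustered into tumor subclones by Louvain community detection on a
    Jaccard-weighted k-nearest-neighbor graph, and the subclone evolutionary
    tree is reconstructed as the minimum spanning tree of consensus subclone
    genotypes, rooted at the most-normal subclone. Ships a ground-truthed
    clone-tree simulator (false positives, allelic dropout, missing bases) and
    the matching recovery and clustering accuracy metrics, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
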
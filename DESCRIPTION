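Package: depf
Title: Dynamic Ensemble Pruning for Single-Cell RNA-Seq Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clustering of single-cell RNA-seq expression matrices by a
    dynamic ensemble-pruning framework (DEPF). Cells are embedded into
    multiple stochastic latent spaces by a hierarchical autoencoder (a
    non-negative kernel autoencoder for gene filtering followed by a
    stacked Bayesian autoencoder), a clustering ensemble is generated in
    each latent space by ultra-scalable bipartite spectral clustering (or
    Louvain/Leiden community detection), and low-quality ensemble members
    are pruned by a bi-objective fruit-fly optimization algorithm whose
    optimization direction is chosen from the silhouette coefficient of an
    initial consensus. The pruned ensemble is merged by locally weighted
    co-association consensus clustering. Includes NMI/ARI external
    validation, a mean-silhouette cluster-number estimator, and seeded
    generators of synthetic scRNA-seq counts for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
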
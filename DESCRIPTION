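Package: connectoscan
Title: Multiscale Statistical Comparison of Connectome Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: k-sample statistical hypothesis tests for identifying signal
    edges, vertices, and communities across phenotype-labeled populations of
    connectomes defined on a shared vertex set. Edge-scale inference uses the
    unbiased k-sample distance correlation under an independent-edge model;
    vertex-scale inference applies Hotelling's T-squared or one-way MANOVA
    (Pillai's trace) to latent positions estimated jointly by the omnibus
    spectral embedding of a random dot product graph; community-scale
    inference compares stochastic-block-model summaries with distance
    correlation and Pearson's chi-squared after Otsu binarization; the global
    scale compares whole-brain embeddings through Frobenius dissimilarities
    and classical multidimensional scaling. Includes family-wise error rate
    control, simulation generators for each topological scale, competitor
    methods (multivariate distance matrix regression, the network-based
    statistic, graph-statistic vertex profiles), and benchmark drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
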
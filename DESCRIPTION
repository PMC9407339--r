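Package: graphsel
Title: Multiscale Graph-Signal Selection for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cluster-free, multiscale feature selection for signals on
    weighted cell-similarity graphs, aimed at single-cell transcriptomics.
    Genes are treated as graph signals and ranked by three complementary
    spectral methods: eigenscores (alignment with low-frequency Laplacian
    eigenvectors), the multiscale Laplacian score driven by continuous-time
    random walks with Markov-stability scale detection, and the persistent
    Rayleigh quotient on Kron-reduced (persistent) Laplacians of filtered
    graphs for trajectory bifurcations. Includes readers for common
    expression-matrix formats, seeded synthetic benchmark generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
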
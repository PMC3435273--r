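Package: rbnevolve
Title: Darwinian Evolution of Random Boolean Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Darwinian evolution of populations of random
    Boolean gene regulatory networks. Genes carry explicit regulatory
    regions (binding sites) and truth tables; networks mutate by
    binding-site gains and losses, grow by gene duplication followed by
    divergence, and are filtered by attractor-conservation and
    attractor-innovation selection criteria plus a replication fitness
    based on gene-expression variability or dynamical sensitivity.
    Provides exhaustive attractor-landscape enumeration for small
    networks, perturbation-based attractor search for large ones,
    criticality diagnostics (annealed and exact network sensitivity,
    Derrida maps), lineage tracking with survival-time statistics,
    gene-knockout robustness assays, and lossless JSON/TSV/GraphML
    serialization of networks and populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
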
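Package: hierbaps
Title: Hierarchical Bayesian Clustering of Haploid Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies population structure in haploid multiple sequence
    alignments with a collapsed Dirichlet-multinomial partition model. The
    marginal likelihood of a partition, with per-cluster allele frequencies
    integrated out analytically, is maximised by a greedy stochastic search
    (individual reassignment, cluster merging and complete-linkage subgroup
    relocation), and the search is applied recursively within each discovered
    cluster to reveal structure at several nested resolutions. Includes a
    singleton-site filter for SNP alignments, writers for partition tables,
    log marginal likelihood logs and phylogenetic tip-annotation tables, and a
    synthetic-alignment generator with planted (optionally nested) clusters
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 3.5)
Imports:
    ape,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
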
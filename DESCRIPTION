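Package: micc
Title: Mutual Information Consensus Clustering of Gene Co-Expression Modules
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies gene co-expression modules that are conserved across
    multiple independently clustered transcriptomic datasets. Module overlaps
    between per-dataset genomic partitions (e.g. WGCNA output) are scored by
    the additive terms of the mutual information of partitions, thresholded by
    MI positivity, and assembled into a k-partite information graph. Cross-
    dataset triangles (k-cliques) in that graph mark conserved modules; a
    triangle graph clustered by greedy modularity maximization yields
    communities, and each community defines a disjoint consensus gene cluster
    via within-dataset unions intersected across datasets. Also provides module
    eigengenes with subset-specificity statistics (Kruskal-Wallis screening,
    directional Wilcoxon rank-sum tests with Bonferroni correction, hub-gene
    enrichment), Stanford PCL / partition-table / GEXF input-output, and a
    synthetic multi-cohort generator with planted conserved, split and
    subset-shifted modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io-pcl.R'
    'io-partition.R'
    'io-gexf.R'
    'mip.R'
    'consensus.R'
    'eigengene.R'
    'subset-stats.R'
    'synthetic.R'
    'pipeline.R'
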
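Package: HiCGeneNet
Title: Gene-Centric Multi-Experiment Hi-C Contact Graphs: Storage,
    Exploration and Network Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An embeddable store and analysis toolkit for gene-centric
    Hi-C chromatin contact networks spanning multiple experiments. Genes
    are nodes stored exactly once; contacts are read-count-weighted,
    probability-scored edges partitioned by experiment label. Provides
    parsers for gene-pair contact tables, BED annotation, binned contact
    matrices and gene-value overlays; a progressive gene-centric
    exploration engine whose session state is a reproducible query
    pattern; graph analytics (weighted Louvain community detection,
    PageRank, betweenness, closeness, clustering coefficients, shortest
    paths in hop and probability modes, per-gene neighbourhood Jaccard);
    cross-experiment comparison (edge-set Jaccard matrices, degree
    tables, community profiles, adjusted Rand agreement); omics-overlay
    group statistics (Welch t, with a compatibility p-value convention);
    a synthetic contact-network generator with planted communities and
    controlled rewiring; and writers for graph-database bulk-import CSV
    and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
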
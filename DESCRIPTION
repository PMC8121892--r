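Package: riverdna
Title: Catchment-Scale Fish Biodiversity Analysis from eDNA Metabarcoding Read Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for environmental DNA (eDNA) metabarcoding
    surveys of fish communities across river catchments. Starts downstream of
    taxonomic assignment, from per-sample taxon read-count tables: applies
    contamination-minimisation filters (per-sample low-frequency threshold and
    negative-control subtraction), merges field replicates and primer sets into
    site-by-taxon community matrices, computes along-network river distances,
    alpha diversity (richness, Poisson distance-decay regression, species
    accumulation curves, environmental PCA), incidence-based beta diversity
    (Jaccard dissimilarity partitioned into turnover and nestedness) with
    Mantel permutation tests, and biogeographical clustering (Canberra
    distance, Ward, k-means, PAM and DIANA) validated by internal and
    stability measures and the Hopkins clustering-tendency statistic. Includes
    a synthetic-data generator producing dendritic river networks, planted
    community structure and realistic read tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
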
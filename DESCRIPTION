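Package: ampliflow
Title: Parallel Marker-Gene Microbiome Profiling and Downstream Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, scriptable pipeline for marker-gene (16S rRNA
    amplicon) microbiome data: read assignment against a reference pack,
    copy-number-corrected taxonomic profiles from kingdom to species level,
    KEGG-Orthology functional prediction with the Nearest Sequenced Taxon
    Index, alpha diversity (Shannon, Simpson, Chao1) with rank-sum and
    regression statistics, phylogeny-aware and hierarchy-aware beta-diversity
    distances with PCoA/PCA ordination and PERMANOVA/ANOSIM permutation
    tests, rank-sum plus Random-Forest biomarker selection, Spearman
    co-occurrence networks with graph summary statistics, a deterministic
    task scheduler for parallel execution, a synthetic-data generator for
    fully reproducible fixtures, and a static HTML result viewer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    parallel,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
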
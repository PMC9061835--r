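Package: modulomics
Title: Signed Co-Expression Network Inference with Epigenome and Copy-Number Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks (soft-thresholded
    adjacency, topological overlap, module detection, module eigengenes, membership
    and connectivity statistics), ranks hub genes by graph centrality, scores samples
    against genesets with a rank-based single-sample statistic and preranked
    enrichment, integrates promoter DNA-methylation beta-values (probe filtering,
    MAD normalization, module-eigengene correlation, regional-category association)
    and gene-level copy-number calls (decision-tree driver candidates and module
    over-representation). Ships a seeded synthetic-cohort generator that plants the
    modular, methylation-coupled and copy-number-coupled structure the analysis
    assumes, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
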
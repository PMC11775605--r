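Package: morphshift
Title: Evolution of Morph-Biased Gene Expression After the Loss of Sex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for contrasting gene expression between
    cyclically parthenogenetic (CP) and obligately parthenogenetic (OP)
    aphid lineages. Classifies genes by morph bias and tissue bias on an
    independent outgroup dataset using genewise negative-binomial exact
    tests, quantifies per-class OP-to-CP expression shifts with Wilcoxon
    signed-rank tests, and compares genetic (Nei distance, neighbour
    joining, PCA) versus transcriptomic divergence between reproductive
    modes with Mantel and Mann-Whitney tests. Includes TMM normalization,
    CPM filtering and a synthetic-data generator that emulates the study
    design so the full pipeline is testable without any download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
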
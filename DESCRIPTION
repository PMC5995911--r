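Package: bivalentr
Title: Bivalent Chromatin and Histone-Variant Occupancy Analysis for ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative, tidyverse-styled toolkit for promoter-centred
    ChIP-seq analysis in embryonic stem cells: depth normalization of tag
    collections, promoter and TSS-anchored occupancy quantification,
    knockdown-minus-control delta matrices and average profiles, a Poisson
    background peak caller, consensus-region overlap and Venn statistics,
    bivalent (H3K4me3 + H3K27me3) promoter classification with
    expression-based Up/Other splitting, a weighted running-sum gene-set
    enrichment statistic with permutation nulls, and the small reporting
    statistics used alongside (comparative-CT qPCR quantification, unpaired
    t and Wilcoxon tests, Benjamini-Hochberg adjustment, quantile-based
    alkaline-phosphatase colony categorization). A seeded synthetic
    chromatin-state generator emulates multi-mark, two-condition tag data
    over active/bivalent/silent promoter archetypes with known ground truth,
    so the whole pipeline is exercisable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
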
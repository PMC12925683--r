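Package: RareTriplet
Title: Rare Loss-of-Function Variant Triplet Analysis in Small Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting and statistically assessing shared
    rare loss-of-function variants in small, deeply phenotyped cohorts. Provides
    a synthetic diploid cohort simulator with planted rare stop-gain haplotypes,
    Balding-Nichols population structure and Mendelian pedigree pairs;
    annotation-driven loss-of-function variant prioritization from VCF;
    KING-robust moment kinship estimation with minor-allele-frequency strata;
    Hardy-Weinberg-normalized principal component analysis; windowed pairwise
    linkage disequilibrium (composite r-squared and EM-based D-prime) with
    perfect-LD partner detection; and the rarity statistics for a shared-variant
    carrier trio: exact hypergeometric carrier-enrichment test against reference
    population counts, random trio-occurrence probability, false discovery rate
    estimate, and conservative Bonferroni adjustment under genome-wide
    loss-of-function test counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, VariantDetection, StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
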
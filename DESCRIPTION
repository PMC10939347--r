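Package: clonescan
Title: Clonal Variability Analysis for Whole-Genome Sequenced Clone Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify intra-varietal (clonal) genomic variability in
    panels of vegetatively propagated, highly heterozygous plants from
    multi-sample variant calls. Implements a post-calling variant filter
    cascade (depth, quality-by-depth, biallelic, SNP-near-INDEL spacing,
    INDEL spacing and length, missingness), classification of variants into
    varietal (shared) versus clone-polymorphic and clone-unique genotypes,
    windowed nucleotide diversity, Watterson's theta and Tajima's D with
    covered-bases accounting, KING-robust kinship and genotype PCA,
    rate-threshold classification of low/high mutation-density regions,
    construction of control/high/very-high mutation sequence sets for motif
    enrichment, a simplified HIGH-impact variant-effect classifier over GFF3
    gene models, single-linkage clustering of transposable-element insertion
    pinpoints into shared events, and a synthetic clone-population generator
    that emulates the statistical structure of such panels so the whole
    pipeline can be exercised end to end under a fixed seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    withr,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
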
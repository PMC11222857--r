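Package: rohkit
Title: Runs of Homozygosity and Genomic Inbreeding from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of runs of homozygosity (ROH) in
    SNP-array genotypes via a PLINK-style sliding-window scan with the Lencz
    minimum-window-size formula, ROH length classes, and descriptive summaries
    per individual, chromosome and cohort. Computes four genomic inbreeding
    coefficients (F_ROH, F_GRM, F_HOM, F_UNI), their Pearson correlations and
    per-generation trends; calls ROH islands from standardized per-SNP ROH
    incidence; annotates islands with genes (GFF3) and QTL records
    (Animal-QTLdb GFF dialect) and tests QTL trait-class enrichment by
    hypergeometric test with Benjamini-Hochberg adjustment. Includes PLINK
    text and binary genotype input/output with quality-control filters (call
    rate, exact Hardy-Weinberg test, minor allele frequency, autosomes only)
    and a pedigree gene-dropping simulator with recombination that tracks
    founder haplotypes, so true autozygous segments and pedigree inbreeding
    coefficients are known for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
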
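Package: twinscan
Title: Selection Scans and Rare-Variant Screening for the Cattle Twinning Trait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic toolkit for dissecting a rare reproductive
    trait (twin calving) in structured cattle cohorts. Reads biallelic SNP
    genotypes from VCF with per-sample metadata, applies the standard
    site- and sample-level filters (minor allele frequency, missingness,
    exact Hardy-Weinberg test), and computes identity-by-state distances,
    a VanRaden-style genomic relationship matrix, principal components and
    neighbor-joining trees, PLINK-style runs of homozygosity with genomic
    inbreeding coefficients, and linkage-disequilibrium decay curves.
    Selection signatures are scanned in sliding windows via the
    Weir-Cockerham Fst estimator and the log2 nucleotide-diversity ratio
    between a twin cohort and controls; top-quantile windows are merged
    into regions whose union or intersection feeds a rare-allele screen
    (rare in every control population, sufficiently frequent and
    well-genotyped in the twin cohort) followed by gene-context
    annotation. A seeded synthetic-cohort generator with planted sweeps,
    rare twin-enriched variants and homozygous tracts provides ground
    truth for recovery testing of the whole pipeline.
License: MIT
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
    vcfR,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
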
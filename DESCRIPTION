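Package: bsamapr
Title: Bulked Segregant Analysis Mapping of Pooled Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for mapping a major trait locus from pooled sequencing of
    extreme-phenotype bulks (BSA-seq) in a biparental cross. Reads a
    multi-sample VCF with per-sample allele depths for two parents and two
    offspring pools, applies depth and parental-homozygosity filters, and
    scans the genome with two association statistics: the SNP-index and its
    between-pool difference Delta(SNP-index), and the Euclidean distance
    between pooled base-frequency vectors. Candidate regions called by the
    two methods are intersected, variants inside them are annotated for
    location and coding effect against a gene annotation and reference
    sequence, and candidate genes are prioritized by tissue expression.
    A KASP (kompetitive allele-specific PCR) toolkit designs allele-specific
    primer assays under melting-temperature, GC, product-length and
    copy-number constraints, calls genotypes from two-channel fluorescence,
    and tests genotype-phenotype association. A seeded simulator generates
    F2 pooled-sequencing datasets (VCF, GFF3, FASTA, phenotypes, truth set)
    with an EMS-biased mutation spectrum so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
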
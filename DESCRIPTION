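Package: strainsnp
Title: Strain-Aware SNP Calling from Long-Read Metagenomic Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-locus statistical SNP calling for long-read metagenomic
    data. Aligned reads are converted window by window into binary
    read-by-locus matrices; correlated candidate loci are grouped by
    chi-square tests and complete-linkage clustering, and each group's
    all-non-reference pattern is validated with a union-bound significance
    test on the probability that independent sequencing errors alone
    produce it. Isolated SNPs are recovered with an exact binomial error
    model, high-noise loci by correlation with confirmed variants, and
    multi-allelic sites by iterative masking and re-calling. Includes a
    deterministic multi-strain read simulator with ground-truth variants
    so the whole pipeline is testable without external data, and writes
    standard VCF v4.2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
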
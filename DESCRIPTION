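Package: gradscan
Title: Trait-Specific Selection Signature Scans from Phenotypic Gradient Population Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps loci associated with a quantitative trait by scanning for
    selection signatures across nested high/low phenotype population pairs.
    Builds three phenotypic gradient differential population pairs from a
    sample-by-trait table, scans each pair with the per-SNP Weir-Cockerham
    fixation index and unnormalized cross-population extended haplotype
    homozygosity (XP-EHH), runs a within-population integrated haplotype
    score (iHS) scan with 50 kb window averaging, converts statistics to
    empirical-rank p-values, and calls trait-specific signatures as SNPs
    that are genome-wide top-1% in all three pairs with a monotone gradient
    of the statistic. Includes SNP-chip quality control, linkage
    disequilibrium decay summaries, genomic region merging and flanking,
    BED interval overlap, and a founder-mosaic simulator of phased SNP
    panels with planted swept QTL for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
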
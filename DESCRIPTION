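Package: driftscan
Title: Temporal Wright-Fisher Selection Scans in Small Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects loci under recent selection from genomic time-series data
    in small populations. For each SNP, a hidden-Markov Wright-Fisher likelihood
    compares drift alone against drift plus genic selection, yielding a
    maximum-likelihood selection coefficient and a likelihood-ratio test
    p-value. The package also provides the standard SNP filtering protocol for
    temporal RAD-seq panels (minor allele frequency, observed heterozygosity,
    missingness, linkage-disequilibrium pruning), per-population genome scans
    with Benjamini-Hochberg FDR control, calling of selection-signature regions
    and gene-proximity annotation from GFF3, plus a forward simulator of
    temporally sampled genotype panels with known truth for power and
    false-positive-rate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
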
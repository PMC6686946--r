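Package: enhancersweep
Title: Scanning Enhancer Regions for Signatures of Recent Positive Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for detecting recent positive selection on
    short regulatory regions (enhancers) from phased population genotypes.
    Computes four region-level selection statistics (Tajima's D, weighted
    Weir-Cockerham F_ST, H12 haplotype homozygosity, and the unstandardized
    nS_L haplotype tract statistic), builds neutral null distributions by
    coalescent simulation under a three-population out-of-Africa demographic
    model with migration and exponential growth, converts observed values to
    empirical p-values, and runs the downstream comparative layer
    (tissue-breadth classification, pairwise Kolmogorov-Smirnov tests with
    Bonferroni correction, group rankings, annotation-overlap chi-squared
    tests with Yates correction, and complete-LD SNP expansion against a
    trait catalog). Includes a fully ground-truthed synthetic-data generator
    that plants hard and soft selective sweeps by founder-haplotype copying,
    so the whole pipeline can be exercised and validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
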
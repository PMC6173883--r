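Package: coassocnet
Title: Co-Association Networks for Multivariate Genotype-Environment
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and interprets modules of SNPs adapting to distinct
    environmental factors from landscape genomic data.  Provides per-population
    allele-frequency computation with SNP quality filtering, uncorrected and
    structure-corrected genotype-environment association statistics (Spearman
    rank correlations and conjugate linear-model Bayes factors on
    covariance-whitened allele frequencies), top-candidate gene and SNP
    detection, co-association distance matrices with Ward clustering and
    threshold-graph modules, galaxy biplots with bivariate-normal prediction
    ellipses, linkage-disequilibrium summaries, a forward-time recurrence
    simulator of haploid SNPs on a deme grid under isolation-by-distance and
    range-expansion demographies with spatially varying selection, and tools
    for evaluating candidate-detection criteria against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
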
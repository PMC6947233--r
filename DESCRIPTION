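Package: divscan
Title: Genomic Divergence and Selection-Signature Scans for Two
    Subpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects genomic divergence between two subpopulations of a
    single breed or cohort, as arises when breeders specialize one breed
    towards different disciplines. Provides genotype and phased-haplotype
    input (PLINK binary, VCF), marker quality control with LD pruning,
    population-structure inference (principal coordinates analysis,
    K-means/BIC cluster selection, discriminant analysis of principal
    components with cross-validated PC retention), dual selection scans
    (per-SNP Nei fixation index with an empirical outlier threshold, and
    cross-population extended haplotype homozygosity with a Gaussian
    p-transform and Benjamini-Hochberg FDR), concordance-based candidate
    region construction with gene and QTL annotation, and a forward
    Wright-Fisher simulator of diverging subpopulations with planted
    selective sweeps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
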
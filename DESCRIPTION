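Package: gpgwas
Title: Bayesian Genome-Wide Association and Genomic Prediction for
    Half-Sib Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome regression analysis of quantitative traits in
    livestock populations with half-sib family structure.  Implements the
    BayesCpi Gibbs sampler for SNP association with permutation-derived
    genome-wise significance thresholds, average-information REML for
    variance components and heritability under an animal model with
    contemporary-group random effects, VanRaden (method 1) genomic and
    pedigree numerator relationship matrices, and genomic prediction by
    GBLUP, pedigree BLUP and Bayesian marker effects evaluated with
    sire-family-disjoint cross-validation and realized accuracy.  A
    synthetic-data generator emulating genotype, pedigree, fixed-effect
    and trait structure supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
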
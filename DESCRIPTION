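Package: snpvus
Title: Multi-Class SNP Classifiers, Volume Under the ROC Surface, and
    Sample Size Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimal Bayes and linear classifiers for coded SNP genotype
    data (0/1/2 minor-allele counts) under Hardy-Weinberg equilibrium,
    with Gaussian approximations to their probabilities of correct
    classification expressed as multivariate normal orthant
    probabilities.  Classifier performance is summarised by the area
    under the ROC curve (AUC, two classes) or the volume under the ROC
    hypersurface (VUS, three or more classes), computed by a stochastic
    threshold search combined with an incremental convex-hull volume
    engine.  An integer bisection search determines the smallest
    per-class sample size for which the VUS of the estimated classifier
    comes within a user-chosen tolerance of the VUS attainable with
    known allele frequencies, yielding learning curves for study
    planning.  Includes simulators for Hardy-Weinberg genotype data, a
    Kendall tau screen for extracting pairwise-independent SNP subsets,
    and TSV/VCF genotype input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    mvtnorm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
LinkingTo: Rcpp
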
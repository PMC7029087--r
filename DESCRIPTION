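Package: hybridscan
Title: Hybrid Detection and Morphometric Discrimination for Flat Periwinkles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-calibrated detection of hybridization between the flat
    periwinkles Littorina fabalis and L. obtusata from codominant microsatellite
    genotypes, mitochondrial haplotypes and shell/genital morphology. Provides a
    Bayesian two-population admixture sampler (membership coefficients Q), a
    six-class genotype-frequency model (parentals, F1, F2 and backcrosses),
    HybridLab-style hybrid genotype simulation with threshold calibration (TQ,
    TPp) that minimizes pure/hybrid misclassification, statistical-parsimony
    haplotype networks with clade-based introgression accounting, and
    landmark-based geometric morphometrics (generalized Procrustes analysis
    with sliding semilandmarks, permutational linear models with residual
    randomization, and discriminant analysis with leave-one-out
    cross-validation). A synthetic-data generator reproduces the statistical
    structure of the study system so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    ape,
    geosphere,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vegan
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
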
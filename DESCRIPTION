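Package: morphoconv
Title: Landmark-Based Cranial Shape Analysis and Tests of Phenotypic Convergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a complete landmark-based comparative analysis of
    cranial shape and predatory ecology: generalized Procrustes alignment of
    3D landmark configurations (with optional bending-energy semilandmark
    sliding), principal-component ordination and phylomorphospace projection,
    multivariate phylogenetic signal (Kmult), distance-based phylogenetic
    generalized least squares with residual-randomization inference,
    canonical-variates discrimination of relative prey-size classes with
    leave-one-out validation, UPGMA candidate selection, and dual tests of
    phenotypic convergence: the distance-based C1-C4 metrics with a
    Brownian-motion simulation null and the phenotypic-vector angle (theta)
    test with a tip-state shuffling null, combined under Benjamini-Hochberg
    false-discovery control into a maximal-convergence decision rule. A
    synthetic-study generator produces trees, specimen-level landmark data,
    and ecology tables so the whole pipeline is testable without any
    specimen downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    phytools,
    picante,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
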
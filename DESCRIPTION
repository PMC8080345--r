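Package: diplomorph
Title: Geometric Morphometrics for Genus Discrimination and Subfossil
    Classification from 3D Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete landmark-based geometric-morphometric workflow for
    discriminating taxa from 3D landmark configurations and assigning
    specimens of unknown affinity to reference groups. Implements
    generalized Procrustes superimposition with sliding semilandmarks
    (Procrustes-distance criterion) and bilateral symmetrization, principal
    component morphospaces with projection of unknown specimens, thin-plate
    spline warps, Procrustes ANOVA with residual-randomization permutation
    tests, multivariate phylogenetic signal (K.mult), canonical variate
    analysis with leave-one-out cross-validation, and classification of
    unknowns by Mahalanobis distance with typicality and posterior
    probabilities. Includes a synthetic-data generator that emulates the
    statistical structure of a bilateral cranial-element study (Brownian
    shape evolution across genera, within-species noise, allometry and
    left-right asymmetry) so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    MASS,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
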
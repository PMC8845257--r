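Package: ecomorphr
Title: Naive Ecomorph Discovery from Microhabitat Descriptors and Linear Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discover and validate ecomorphs -- groups of species whose
    morphology evolved under shared microhabitat demands -- without assigning
    species to named categories a priori. Species are clustered from binary
    microhabitat descriptors (Jaccard distances, principal coordinates,
    Gaussian-mixture BIC model selection with a first-plateau rule, k-means),
    linear measurements are reduced, log-transformed and size-corrected against
    an isometric size axis, and the ecology-morphology association is tested
    with phylogenetic comparative statistics: two-block phylogenetic partial
    least squares, generalized least squares MANOVA with randomized-residual
    permutation, distance-based pairwise group tests, and Blomberg's K
    (univariate and multivariate) phylogenetic signal. A synthetic-data module
    generates pure-birth trees, clustered Bernoulli microhabitat profiles and
    Brownian-motion morphologies so that every stage of the pipeline can be
    verified by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
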
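Package: repnets
Title: Intersubject Representational Convergence and Informational Network RSA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-searchlight representational similarity analysis for
    discovering group-convergent neural representations and querying them for
    abstract category knowledge. Builds item-level dissimilarity matrices at
    every node of a subdivided-icosahedron cortical surface, maps within-group
    intersubject dissimilarity-matrix correlations with data-driven
    negative-extent noise thresholding and surface cluster correction,
    partitions the surviving regions into informational networks by Ward
    clustering with split-half cross-validated selection of the cluster count,
    and scores each network against a mechanical-category model and an HMAX C1
    visual-similarity control model via normalized correlation and one-sample
    t-tests. Includes a synthetic-study generator (meshes, planted
    representational structure, line-drawing stimuli) so that every stage is
    verifiable by parameter recovery, plus nonmetric multidimensional scaling
    item-space rendering with 95 percent concentration ellipsoids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mclust,
    igraph,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
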
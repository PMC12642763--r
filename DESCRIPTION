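Package: deindfmri
Title: De-Individualization of Parcellated Task fMRI via Whitening and
    Bures Geometry
Version: 0.1.0
Authors@R:
    person("Dana", "Whitfield", email = "dwhitfield@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing region-parcellated task fMRI scans and for
    removing individual-identifying structure from them. Task scans are
    compared directly with the Frobenius distance, or as functional
    connectomes with the Bures distance on positive semidefinite matrices.
    A two-stage de-individualization (row de-meaning followed by Mahalanobis
    whitening against the parent-scan covariance) yields the dM dissimilarity,
    which exposes task-related signal instead of subject identity. Distance
    matrices are embedded with Isomap (k-nearest-neighbour graph, graph
    geodesics, classical multidimensional scaling) and clusterings of the
    embedding are scored against subject and task labels with the adjusted
    Rand score and adjusted mutual information. A seeded synthetic-cohort
    generator emulates the statistical structure these distances detect, so
    the whole pipeline is testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
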
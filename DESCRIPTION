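Package: carapace
Title: Morphometrics and Scaling Analysis of Tessellated Boxfish Carapaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the tessellated armor (carapace) of
    boxfishes from labeled 3D segmentations. Builds region-adjacency
    graphs of scutes, constructs smoothed dual surfaces, and computes
    per-scute morphometrics (neighbor counts, volume, plane-based area,
    thickness, width, aspect ratio, Gaussian and mean surface curvature).
    Includes allometric scaling analyses against carapace surface area
    (log-log ordinary least squares and Poisson regression with
    confidence intervals), size normalization by fitted exponents,
    curvature-based edge/flat region classification, scute shape
    frequency tables, and principal-component based hierarchical
    clustering of scute types. A synthetic-carapace generator produces
    closed boxfish-like tessellated surfaces and voxelized label fields
    with controllable cross-sectional geometry, openings, and
    curvature-correlated thickening for validation and simulation
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    MASS,
    ape,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
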
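Package: fluorsep
Title: Separability Indices for Fluorescent-Fingerprint Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for judging how well a fluorescence-fingerprint measurement
    condition (an added fluorophore) discriminates a panel of samples in
    principal-component score space. Implements quenching normalization of
    replicate emission spectra against blank wells, mean-centred PCA, per-sample
    Student confidence ellipses with an exact conic-quartic crossing count
    (CrN), a convex-hull relative-position index (RP) built from scalar
    projections of boundary points, Mahalanobis-membership total sensitivity,
    quadratic-discriminant and support-vector training sensitivities, metric
    cross-correlations and a rank-sum overall rating of conditions, together
    with seeded synthetic-data generators and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    e1071
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
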
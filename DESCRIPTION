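Package: cpfosr
Title: Bayesian Function-on-Scalar Regression with a Canonical Polyadic Tensor Basis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast Bayesian estimation of population-level brain activation maps
    from multi-subject 3D contrast volumes. A canonical polyadic (CP) tensor
    decomposition of the 4D (space by subject) contrast tensor yields a spatial
    basis; subject scores are regressed on covariates with a conjugate
    Matrix-Normal/Inverse-Wishart model; posterior draws are projected back to
    voxel space where simultaneous band scores (SimBaS) control the
    experimentwise error rate and significant voxels are reported as connected
    clusters. Includes cross-validated CP rank selection, a per-voxel GLM for
    subject-level contrast maps, a synthetic-data generator with known low-rank
    truth, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
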
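Package: scnmap
Title: Seed-Based Gray-Matter Structural Covariance Network Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based mapping of gray-matter structural covariance
    networks from modulated gray-matter density volumes. Builds seed
    masks (spheres at MNI coordinates, atlas-label regions, hippocampal
    long-axis bands), extracts per-subject seed values, fits
    mass-univariate multiple-regression models with nuisance covariates,
    maps within-group covariance with Benjamini-Hochberg voxel-level
    correction and an extent filter, maps between-group slope
    differences with a dummy-coded interaction model and
    random-field-theory cluster-level correction, reports clusters with
    atlas-labelled peaks, and relates peak volumes to cognitive scores
    by partial correlation. Includes a synthetic-cohort simulator with
    known covariance structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
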
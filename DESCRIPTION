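Package: dfamri
Title: Director Field Analysis of White Matter Geometry from Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the geometry of the white matter fiber orientation field
    from diffusion tensor MRI using director field analysis: voxelwise splay,
    bend, twist and total distortion indices computed from the principal
    eigenvector field with antipodal (sign-free) semantics. Includes log-linear
    diffusion tensor fitting with FA/MD derivation, mask-restricted voxelwise
    group inference by Freedman-Lane permutation with threshold-free cluster
    enhancement and family-wise error correction, a leave-one-out consistency
    procedure for small groups, atlas-based feature extraction with voxel-count
    inclusion rules, normality-gated clinical correlation analysis with
    Benjamini-Hochberg correction, and a nested cross-validated stacked-ensemble
    classifier with permutation feature importance. Analytic tensor-field
    phantoms (uniform, splay, bend, twist) and a synthetic two-group cohort
    generator provide ground-truth surfaces for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    glmnet,
    ranger,
    e1071,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
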
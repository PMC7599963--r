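Package: microtract
Title: White-Matter Microstructure Mapping and Skeleton-Based Group
    Inference for Single-Shell Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes diffusion-tensor scalar maps (fractional anisotropy,
    mean, axial and radial diffusivity) and apparent ensemble-average-
    propagator scalars (return-to-origin, return-to-axis and return-to-plane
    probabilities) from single-shell diffusion-weighted MRI, using both the
    Gaussian closed forms in the tensor eigenvalues and a single-shell
    spherical-harmonic construction that assumes radial independence of the
    diffusion signal.  Provides tract-skeleton group comparison in the style
    of tract-based spatial statistics: a mean-FA ridge skeleton, projection
    of subject maps onto the skeleton, threshold-free cluster enhancement
    with permutation-based family-wise-error correction (with Freedman-Lane
    handling of nuisance covariates), and atlas region reporting.  Includes
    a synthetic cohort generator (tensor-field phantoms, Rician noise,
    seeded group effects and demographics) so the full pipeline can be
    exercised and validated without patient data, plus cohort-table and
    region-of-interest statistics (chi-square, Fisher, t, Mann-Whitney,
    Kruskal-Wallis, Spearman with Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    pracma,
    stats,
    utils,
    withr,
    car
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
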
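Package: intgrad
Title: Intrinsic Neural Timescales and Functional Connectivity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates voxelwise intrinsic neural timescales (INT) from
    resting-state fMRI time series as the sum of autocorrelation values over
    the initial positive period of the ACF, builds functional-connectivity
    (FC) gradients by sparsifying voxel-pair correlation matrices, applying a
    cosine-similarity affinity kernel and diffusion-map embedding, relates
    INT and gradient topographies, projects maps across structures
    (argmax and top-k projections), and quantifies map stability and
    hierarchy stability with Fisher-z and subset-resampling statistics.
    Includes a synthetic multi-subject, multi-run AR(1) generator with a
    planted connectivity topography for ground-truth recovery testing, and
    NIfTI-based file interfaces for real data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
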
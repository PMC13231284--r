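Package: dwiseg
Title: Segmentation of Diffusion-Weighted MRI with Arbitrary q-Space Samplings
Version: 0.1.0
Authors@R:
    person("dwiseg", "developers", email = "dwiseg@example.org", role = c("aut", "cre"))
Description: Anatomical segmentation of diffusion-weighted MR images acquired
    with arbitrary q-space samplings. A per-voxel, permutation- and
    antipodal-sign-invariant set encoder turns a variable-length collection of
    (b-vector, b-value, signal) measurements into a fixed-length diffusion
    embedding, which a 2.5D multi-view convolutional segmenter consumes
    together with a mean b0 image. Includes a synthetic diffusion-tensor
    phantom generator (digital brain phantoms with Rician noise), q-space
    scheme generation and maximum-angular-coverage sub-sampling, NIfTI-1 and
    FSL bvec/bval input/output, Dice and percentile-Hausdorff evaluation with
    label merging/grouping, and exact one-sided Wilcoxon signed-rank tests, so
    that the complete pipeline (simulate, pretrain, train, segment, evaluate)
    is trainable and testable at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
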
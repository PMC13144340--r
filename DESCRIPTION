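Package: iscpipe
Title: Inter-Subject Correlation Analysis of Framed Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise inter-subject correlation (ISC) analysis for naturalistic
    fMRI experiments with framed stimuli: voxel-wise Fisher-z pair maps,
    unmatched-segment baseline correction, condition contrasts with
    block-restricted permutation inference, threshold-free cluster enhancement
    (TFCE) and family-wise error control, generalized Pareto tail refinement of
    permutation p-values, and dyadic regression of synchrony on covariate
    proximity. Includes a synthetic BOLD cohort generator with known
    ground-truth coupling for end-to-end validation, and linear-model helpers
    for framing effects on self-reported emotion and sharing behavior.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
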
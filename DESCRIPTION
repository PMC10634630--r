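Package: faceRSA
Title: Representational Similarity and Decoding Analyses of Face Race and
    Identity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) and
    signal-detection decoding of face race and identity from layered
    feature arrays (such as deep-network activations) and from multi-voxel
    fMRI response patterns. Builds stimulus-by-stimulus Pearson similarity
    matrices, performs one-versus-rest race decoding and same/different
    identity decoding via ROC AUC converted to d-prime, controls the
    familywise error rate over layers with maximum-statistic permutation
    tests, correlates feature similarity with behavioural same/different
    judgements (with Fisher z machinery for comparing correlations),
    extracts regions of interest from statistical volumes by thresholded
    flood fill, and runs leave-one-participant-out pattern-similarity MVPA
    and fMR-adaptation contrasts. Includes synthetic-data generators that
    plant the statistical structure these analyses assume, so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
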
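Package: mtpbci
Title: Motion Trajectory Prediction and Multi-Class Decoding of Imagined 3D Arm Movements from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding imagined three-dimensional arm movement
    trajectories from multichannel EEG. Implements a band-power based
    multiple linear regression velocity decoder with lag embedding,
    recursive channel selection under leave-one-run-out cross-validation,
    trajectory reconstruction metrics, an assisted closed-loop feedback
    simulator, time-varying target classification accuracy with permutation
    nulls, and a filter-bank common spatial patterns comparator classifier
    with mutual-information feature selection and regularized linear
    discriminant analysis. Includes a synthetic EEG and kinematics session
    generator with known velocity encodings and class-dependent spectral
    patterns so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
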
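Package: motionQC
Title: Head-Motion Assessment and Quality Control for fMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies subject head motion in functional MRI from rigid-body
    realignment parameters. Converts 6-parameter motion trajectories
    (3 translations in mm, 3 rotations in radians) into total-displacement
    series using a reference cortical distance, compares complete versus
    reduced (translation-only, rotation-only) parameter sets, estimates the
    average cortical distance from gray-matter masks, applies motion-scrubbing
    cutoffs, replays motion into phantom time series with high-order B-spline
    resampling to score motion-induced signal change, and partitions
    motion-explained variance with voxel-wise linear models (including the
    24-regressor Volterra expansion and motion-fingerprint regressors).
    Includes seed-deterministic generators for synthetic motion trajectories,
    ellipsoid brain phantoms with gray-matter shells, and motion-corrupted
    4-D series with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
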
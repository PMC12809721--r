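Package: synctap
Title: Synchronization-Continuation Finger-Tapping Analysis for Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for paced finger-tapping experiments with
    synchronization (tone-paced) and continuation (self-paced) conditions
    acquired during fMRI. Builds the trial/phase/tone timeline of the task,
    detects tap events in raw force-sensor traces with auditable exclusion
    rules, computes inter-tap-interval and force series with sliding-window
    moving averages and repeated-measures statistics, fits block GLMs with a
    double-gamma haemodynamic response, and estimates lagged brain-behaviour
    correlations from finite-impulse-response deconvolution with sign-flip
    permutation inference. A calibrated generative simulator (two-level
    timekeeper with linear phase correction, force-pulse rendering, and
    AR(1) BOLD noise) stands in for non-shareable participant data so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
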
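Package: focalroi
Title: Automated Detection of Repetitive Focal Activations in Atrial Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects repetitive focal activation sites ("regions of interest",
    ROI) in multichannel unipolar atrial electrograms recorded with basket or
    PentaRay-style mapping catheters. Implements the full pipeline: catheter
    geometry and neighbor graphs, zero-phase band-pass/notch signal
    conditioning, per-electrode local activation time annotation with channel
    quality gating and unipolar QS-morphology classification, the ROI
    criteria (QS morphology, leading relative to neighbors, at least two
    consecutive repetitions), radial-spread verification, aggregation of
    sequential maps, driver-characterization metrics (consistency, temporal
    stability, recurrence rate), and diagnostic-accuracy statistics with
    exact binomial confidence intervals. A kinematic simulator generates
    ground-truth focal, reentrant, planar and fibrillatory recordings so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
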
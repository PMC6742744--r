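Package: axonmap
Title: Mapping Axonal Arbors from High-Density Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for large-scale mapping of axonal arbors from
    high-density microelectrode array (HD-MEA) recordings: band-pass
    filtering and robust (MAD-based) threshold spike detection, whole-array
    activity and axon-initial-segment mapping, switch-matrix recording
    configuration planning, per-electrode spike sorting, spike-triggered
    average footprint assembly, and axon segmentation from delay maps by a
    local delay-variance statistic with an automatically placed valley
    threshold. Includes an amplitude-threshold reference segmentation,
    mixture-model ROC/AUC and Hausdorff-distance evaluation, and a seeded
    synthetic-data simulator (branching arbors, conduction delays, spike
    waveforms, Poisson firing, Gaussian noise) providing ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    mclust,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
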
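Package: spineclust
Title: Dendritic Spine Plasticity Metrics, Clustered-Change Statistics and
    Intrinsic-Signal Ocular Dominance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies experience-dependent structural plasticity from
    longitudinal two-photon imaging of dendritic spines and from intrinsic
    signal optical imaging of visual cortex. Provides shaft-normalized spine
    size estimation, baseline-referenced normalized size changes bounded in
    [-1, 1], spine density and addition/elimination/turnover rates,
    increasing/decreasing/stable classification, a nearest-neighbour
    spine-pair statistic of spatially clustered plasticity with a
    within-dendrite permutation (Monte Carlo) null, and Fourier extraction of
    per-pixel response amplitude and phase at the stimulus frequency with
    ocular dominance index computation over a smoothed, thresholded binocular
    region of interest. A synthetic-data generator produces spine datasets
    and periodic-stimulus movies with known ground truth so every stage of
    the pipeline can be validated without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
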
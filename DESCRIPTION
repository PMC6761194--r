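Package: synquery
Title: Probabilistic Query-Based Synapse Detection for Immunofluorescent
    Array Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies synapses of user-declared molecular types
    in multiplexed immunofluorescent array tomography volumes. Raw marker
    channels are converted to per-voxel foreground probabilities under a
    Gaussian background model, declarative queries (presynaptic, postsynaptic
    and optional astrocytic markers with minimum punctum sizes and slice-span
    requirements) are evaluated into synapse probability maps, and thresholded
    detections are summarised as size-binned densities per cubic micron of
    neuropil. Includes DAPI-based neuropil volume masking, van Steensel
    shift-correlation colocalization, wild-type versus knockout cohort
    statistics, and a calibrated synthetic-volume simulator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
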
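Package: vwikit
Title: Artery Segmentation, Centerline Extraction and Curved Planar
    Reformation for 3D MR Vessel-Wall Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated post-processing pipeline for three-dimensional
    magnetic resonance vessel-wall imaging (3D MR-VWI) of the head and neck
    arteries. Provides a synthetic multi-sequence vascular phantom generator
    with ground-truth masks and centerlines; trainable dual-channel
    (black-blood T1WI/T1WI-CE) and single-channel (bright-blood TOF-MRA) 3D
    segmentation-and-recognition networks with probability fusion; centerline
    extraction via topology-preserving skeletonization, distance-field-driven
    minimal-path tracing, anatomical gap bridging and lumen-based refinement;
    straightened curved planar reformation (CPR) with rotation-minimizing
    frames; and evaluation metrics (Dice coefficient, centerline accuracy,
    mean centerline distance, deviation-based quality rubric).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
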
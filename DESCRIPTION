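Package: eeglocate
Title: Curvature-Based Localization and Distance-Profile Labeling of EEG
    Electrodes from MR-Derived Scalp Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated localization and labeling of EEG electrodes
    for simultaneous EEG-fMRI head modeling. Electrodes are detected as
    high-curvature protrusions on a triangulated scalp surface extracted
    from T1-weighted MRI (discrete mean-curvature or angle-deficit
    estimators, top-K selection, single-linkage clustering, cluster
    centroids), then labeled by matching each electrode's descending
    sorted vector of distances to all other electrodes (its distance
    profile) against labeled template sets via Pearson correlation, with
    multi-template majority voting and left/right disambiguation against
    the FPZ-OZ midplane. Includes readers and writers for PLY, OFF,
    binary STL and FreeSurfer surfaces and for BESA .sfp, ASA .elc and
    BIDS electrodes.tsv coordinate tables, a synthetic head-phantom
    generator with ground truth for validation, detection-rate and
    TP/FP/FN scoring, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
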
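Package: eaequant
Title: Quantification Pipelines for EAE Gait Kinematics, Histology, and
    Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify recovery in the mouse experimental autoimmune
    encephalomyelitis (EAE) model. Treadmill hindlimb gait kinematics are
    computed from markerless pose-estimation tracks: pixel-to-centimetre
    calibration from a marker rectangle, interior joint angles, swing/stance
    phase segmentation from toe velocity, time normalization of each phase to
    100 samples, averaging into a 200-frame representative step cycle, and
    average-angle and RMS-difference gait metrics. Histology modules quantify
    axonal transection from punctate eYFP fluorescence with grey-matter
    normalized thresholds, white-matter loss from Eriochrome Cyanine/Neutral
    Red staining, and remyelination from area-equivalent g-ratios of
    segmented axons. Gene expression is analysed by the delta-delta-Cq method
    with multi-reference normalization and geNorm M stability; clinical
    scores are summarised as cumulative disease indices compared with an
    exact one-tailed Mann-Whitney U test. Seeded synthetic-data generators
    with exported ground truth make every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
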
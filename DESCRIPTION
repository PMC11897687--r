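Package: beamwalkr
Title: Automated Beam-Walk Phenotyping from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the rodent beam-walk balance assay from
    marker-less pose-estimation keypoint tables. Reads DeepLabCut-dialect
    tracking files, derives beam geometry and calibration from beam markers,
    automates the classical endpoints (time to cross the central beam region
    and threshold-based hindpaw foot-slip detection with temporal merging),
    engineers a normalized posture and balance feature set (pairwise body-part
    distances, joint angles and beam heights summarized by mean, minimum,
    maximum and variance), and discriminates experimental groups with a nested
    leave-one-mouse-out random-forest workflow including recursive feature
    elimination, consensus feature prioritization and cross-cohort transfer.
    Companion statistics (bootstrap feature-overlap significance,
    hypergeometric category enrichment, linear-discriminant projections with
    centroid distances), skeleton visualizations, and a seeded synthetic
    trial generator with full ground truth make the whole pipeline testable
    without any video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
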
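Package: marmoreg
Title: Multimodal CT-MR Fiducial Registration and Stereotactic Coordinate
    Frames for Small-Primate Neuroimaging
Version: 0.1.0
Authors@R:
    person("Marmoreg", "Developers", email = "marmoreg@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-based fiducial registration (MBFR) between
    CT and MR head volumes of small primates, with marker-registration-error
    (MRE) quality control, boundary-based (BBR-style) fine tuning of the
    rigid pose, construction of AC-PC and image-based stereotactic
    coordinate frames from cranial landmarks, frame-bias decomposition
    into pitch/roll/yaw, reproducibility statistics (ICC(1,1), exact
    Wilcoxon signed-rank, coefficients of variation), and a deterministic
    digital head-phantom generator that makes the whole pipeline testable
    without any scan data. Volumes are read and written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
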
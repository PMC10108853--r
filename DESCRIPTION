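Package: archforce
Title: Linking Skeletal Muscle Architecture to In Vivo Force Production
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline relating ultrasound-measured vastus
    lateralis muscle architecture (fascicle length, pennation angle,
    muscle thickness) to knee-extensor force production measured by
    isokinetic dynamometry. Provides torque signal conditioning
    (zero-phase Butterworth filtering, passive/gravity correction,
    moment-arm and PCSA-share force estimation), reconstruction of
    fascicle geometry from dual-probe segmentation coordinates and from
    panoramic fascicle-fragment orientations, force-length and Hill
    force-velocity curve fitting with a bounded curvature parameter,
    joint and muscle work by trapezoidal integration over the common
    iso-velocity phase, and cohort-level Pearson correlation reporting.
    A seeded synthetic-cohort generator with known ground-truth
    contractile properties makes every stage testable end-to-end by
    parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    nortest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
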
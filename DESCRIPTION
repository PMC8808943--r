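Package: ultracart
Title: Femoral Cartilage Thickness from Segmented Ultrasound Contours
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automated measurement of femoral cartilage thickness from
    segmented suprapatellar ultrasound images, and the statistical chain used
    to interpret longitudinal change. A calibrated two-border contour
    (synovial-cartilage and cartilage-bone polylines) is partitioned into
    medial, intercondylar, and lateral regions around a manually marked
    central point; per-region cross-sectional area, bone-interface arc
    length, and mean thickness are computed by polygon clipping and the
    shoelace formula. Test-retest precision is quantified with ICC(2,k),
    the standard error of measurement, and the minimal detectable change at
    90% confidence (MDC90); per-knee longitudinal change is classified as
    thickening, thinning, or no change against MDC90; limb-by-time
    repeated-measures ANOVA and classical two-sample tests cover group
    comparisons. A synthetic phantom and cohort generator with analytic
    ground truth makes every stage testable without image data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    png,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
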
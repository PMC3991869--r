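Package: vestigait
Title: Gait Analysis from Shank-Mounted Gyroscopes in Vestibular Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bilateral shank-mounted gyroscope recordings
    of continuous corridor walking, aimed at quantifying gait asymmetries in
    unilateral vestibular hypofunction (e.g. vestibular neuritis). Computes
    normalized angular velocity (per-axis share ratios and offset-corrected
    pitch angular velocity), detects toe-off, mid-swing, heel-strike and
    mid-stance events per stride, derives stride/stance/swing timing, slope and
    amplitude parameters, estimates cadence from the dominant spectral peaks,
    and compares groups with the normality-routed ANOVA / Kruskal-Wallis,
    LSD / Dunnett T3 and Mann-Whitney workflows common in clinical gait
    studies. Includes a calibrated synthetic walk generator with control and
    vestibular-neuritis presets for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
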
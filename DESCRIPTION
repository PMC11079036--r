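Package: arbbt
Title: Headless Engine and Validation Statistics for an Augmented-Reality
    Box and Block Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A camera-free, fully testable implementation of an
    augmented-reality Box and Block Test (AR-BBT) for upper-limb dexterity
    assessment. Ingests streams of 21-point hand-landmark frames (recorded
    JSONL files or a built-in synthetic hand-motion simulator), detects
    pinch grasps from thumb-index fingertip distance with hysteresis, runs
    the virtual block lifecycle (spawn, grab, carry, divider collision,
    release, score) through timed 60-second trials, and extracts
    per-transfer kinematics. Also provides the companion validation
    statistics: a priori power analysis for a correlation via the Fisher z
    transformation, Pearson correlation with Cohen effect-size
    classification, paired score comparison, cohort eligibility filtering,
    Likert questionnaire summaries, and a bivariate-normal paired-score
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
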
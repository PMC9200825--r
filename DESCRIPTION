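Package: dualcue
Title: Dual-Cue Spatial Attention Experiments with Information-Optimal Feature Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for dual-cue spatial-cueing
    (Posner-type) attention experiments in which the competing peripheral cues
    are small binary patches selected by a constrained maximum-entropy model of
    early vision. Provides patch-statistics estimation from images and
    entropy-constrained feature selection; exact trial-schedule generation for a
    covert-attention (2AFC contrast discrimination) task and a gaze-orienting
    (saccade) task; synthetic psychophysical and oculomotor observers; maximum
    likelihood cumulative-Gaussian psychometric fitting with 80 percent-correct
    contrast thresholds; zero-phase Butterworth filtering, conjoint
    velocity-acceleration saccade detection, and regular/anticipatory saccade
    classification; and the group-level statistics used to summarise such
    experiments (repeated-measures ANOVA, Bonferroni-corrected paired tests,
    Friedman/Conover rank tests, two-proportion z tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
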
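Package: whiskeye
Title: Coordinated Whisker and Eye Movement Analysis for Head-Fixed Maze Navigation
Version: 0.1.0
Authors@R:
    person("Whiskeye", "Developers", email = "whiskeye@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coordinated whisker and eye movements of
    head-fixed mice navigating a floating plus maze. Converts tracked keypoints
    into normalized whisker angles (circle fit, session-median zeroing,
    trial-range normalization) and normalized pupil positions (ellipse fit,
    eyelid parabola fit, eye-corner projection), detects conjugate saccades by
    a dual-eye speed threshold with a refractory artifact rule, time-normalizes
    behavioral epochs, predicts cued turn direction from whisker asymmetry and
    eye position with per-bin ROC/AUC and a deterministic linear separator with
    shuffle-based unique contributions, and computes saccade-triggered
    whisker-asymmetry correlograms against within-epoch shuffled-timing nulls.
    Includes a synthetic session generator with full ground truth, and
    self-contained nonparametric tests (Mann-Whitney U, Kruskal-Wallis, Dunn's
    post hoc, Bonferroni correction).
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
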
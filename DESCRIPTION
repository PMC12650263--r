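Package: createlab
Title: Multi-Modal Cognitive-Affective Session Scoring and Permutation-Based Validation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores multi-modal digital mental-health sessions and validates them
    statistically. Provides an adaptive sequence-recall (Corsi-style) working-memory
    game engine with session metrics, PSQI and ERQ questionnaire scoring with
    good/poor sleeper classification, lexicon-based sentiment and lexical-diversity
    features for short emotional narratives, spontaneous eye-blink-rate (sEBR)
    detection from eye-opening-ratio time series, valence-arousal quadrant analysis
    with an HVHA arousal-deviation predictor, and a statistical pipeline combining
    two-SD outlier filtering, permutation-based Spearman correlation matrices,
    Mann-Whitney group comparisons and OLS regression with a full diagnostic report.
    A synthetic-cohort generator with planted latent structure makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
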
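Package: vidunder
Title: Human-in-the-Loop Understandability Classification of Patient Education Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the understandability of patient-education
    videos on user-generated content platforms. Implements PEMAT
    (Patient Education Materials Assessment Tool) audio/visual
    understandability scoring, two-view feature extraction from video
    metadata and precomputed content signals (readability, active-voice
    counting, summary/transition lexicons, dictionary-based medical term
    matching), a confidence-thresholded co-training classifier with
    human-oracle arbitration of cross-view conflicts, ranking evaluation
    (precision at K), and a matched-sample causal analysis (coarsened
    exact matching and propensity-score matching with balance diagnostics)
    of the effect of understandability on viewer engagement. A seeded
    synthetic-corpus generator with known ground truth supports
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
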
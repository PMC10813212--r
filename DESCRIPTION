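Package: ssmpipe
Title: Sleep-State Misperception Analysis from Polysomnography and Sleep Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the discrepancy between subjectively reported and
    polysomnographically recorded sleep in insomnia. Provides epoch-based
    hypnogram handling with latency-to-stage measures, sleep-diary ingestion,
    misperception indices (SLm, TSTm, raw sleep-latency discrepancy with a
    10-minute group split), automated stand-ins for visually scored EEG
    measures (micro-epoch alpha density on occipital leads, K-complex
    detection on frontal leads, REM arousal detection with chin-EMG
    confirmation), Markov-chain estimation of stage-transition probabilities
    within the subjective sleep-onset window, and a statistics layer
    (exact Mann-Whitney U with rank-biserial effect size, Spearman rank
    correlation, Shapiro-Wilk normality gate, ordinary least squares and
    backward-stepwise model selection). A synthetic-cohort generator with
    known ground truth emulates hypnograms, EEG and diaries so that every
    stage of the pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
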
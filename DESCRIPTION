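Package: tfsassay
Title: Individualized Assays of Auditory Temporal Fine Structure Coding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating individualized assays of
    auditory temporal-fine-structure (TFS) coding: calibrated synthesis of
    frequency-modulation, interaural-time-difference (ITD) and
    forward-masked frequency-following-response (FFR) stimuli; adaptive
    staircase psychophysics with a lapse-rate ("nonsensory") catch-trial
    score; intertrial-coherence, N1/P2 latency and normalized ITD-growth
    metrics from cortical EEG epochs; polarity-based FFR decomposition into
    envelope and fine-structure components with forward-masking residuals;
    incremental variance partitioning for brain-behavior regression; and a
    synthetic-cohort generator with known latent parameters so that every
    pipeline stage can be exercised end-to-end against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
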
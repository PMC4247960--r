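Package: facexpr
Title: Automated Facial Expressivity Assessment for Parkinsonian Hypomimia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies facial masking (hypomimia) from per-frame facial
    action unit (AU) classifier scores and companion physiological signals.
    Calibrates support-vector-machine decision values into AU intensity
    probabilities via Platt scaling, smooths and segments the intensity time
    series into neutral/onset/apex/offset phases, and computes per-window
    expressivity statistics (total facial activity, intensity of displayed
    AUs, amount of movement change, and the baseline-corrected expressivity
    score). A physiological branch denoises ECG/EMG thin slices by empirical
    mode decomposition, detects R peaks with a piecewise-linear change-point
    segmentation, and derives heart rate, heart-rate variability, and
    baseline-normalized EMG amplitude. Includes a synthetic cohort generator
    with ground-truth annotations (control and three Parkinson severity
    archetypes), group-level statistics (Wilcoxon rank-sum, mixed-design
    ANOVA with post-hoc tests), and a config-driven pipeline over cohort
    manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
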
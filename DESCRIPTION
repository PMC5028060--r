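Package: esmnet
Title: Idiographic Symptom Networks from Experience Sampling Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for n-of-1 clinical network analysis of experience
    sampling (ESM) time series: beep-level data validation and CSV input
    and output, medication-dose based relapse-state segmentation,
    within-day lag-pair construction, state-stratified lag-1 regression
    symptom networks with linear de-trending, Spearman partial-correlation
    sensitivity networks, weighted directed centrality indices
    (strength, closeness, betweenness) with self-loop handling, per-state
    descriptive tables and contrasts, and a seeded synthetic ESM generator
    with state-dependent vector-autoregressive ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
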
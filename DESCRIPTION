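Package: stolfnirs
Title: Block-Design Tower of London fNIRS Simulation and Multilevel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the S-TOL, a block-design Tower of London task for
    prefrontal functional near-infrared spectroscopy (fNIRS). Covers the
    task's combinatorics (the 36-state board graph, minimum-move solver,
    search-depth and goal-hierarchy classification), generation of problem
    banks and the timed block schedule with event markers, behavioral
    scoring, an fNIRS preprocessing chain (modified Beer-Lambert
    conversion, zero-phase FIR low-pass filtering, channel screening,
    sliding-window motion artifact rejection, block segmentation with
    local baselines), channel-wise random-intercept multilevel contrasts
    with between-within degrees of freedom and false-discovery-rate
    correction, a cross-level trait-moderation analysis with simple
    slopes, and a seeded synthetic cohort generator so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
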
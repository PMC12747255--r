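Package: riskensembles
Title: Ensemble and Population Analyses for Risky Decision-Making Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for touchscreen risky
    decision-making experiments with single-cell calcium imaging and fiber
    photometry. Builds task schedules (reward-magnitude discrimination,
    risky-decision test with blockwise punishment probabilities, progressive
    ratio, footshock ladder), computes behavioral metrics (choice percentages,
    latencies, aborts, path lengths, bootstrap latency flags), aligns
    fluorescence traces to behavioral events with per-trial z-scoring,
    identifies event-encoding neural ensembles against circular-shuffle nulls,
    classifies safe-to-risky ensemble remapping (Conserved, Lost, New), and
    provides population-vector correlations, permutation and bootstrap
    time-series tests with consecutive-bin significance, PCA trajectory
    divergence with rotation nulls, linear-classifier decoding controls, and
    control-channel-regressed photometry event statistics. A synthetic-data
    module generates ground-truth-labeled sessions so every stage is testable
    without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
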
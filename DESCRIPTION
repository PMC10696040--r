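Package: respburst
Title: Phrenic and Vagal Nerve Burst Analysis for Respiratory Pattern Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiunit nerve recordings of the respiratory
    central pattern generator. Builds rectified, moving-average integrated traces
    from raw phrenic and vagus nerve activity, detects inspiratory bursts and
    segments the record into inspiratory and expiratory phases, computes
    burst-triggered average waveforms over sliding windows, quantifies drug
    responses as percent-of-baseline time courses and change rates, and applies
    the group statistics (one-sample and paired t-tests, repeated-measures ANOVA
    with Dunnett many-to-one comparisons). Includes a seeded synthetic-signal
    generator with ground truth so the full chain can be validated without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    lme4,
    multcomp
Config/testthat/edition: 3
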
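Package: ercflow
Title: Event-Related Causality Analysis of Directed High-Gamma Interactions
Version: 0.1.0
Authors@R: person("ercflow", "developers", role = c("aut", "cre"),
    email = "ercflow@example.org")
Description: Estimation of event-related causality (ERC) between intracranial
    recording sites from multichannel electrophysiological recordings during a
    cued overt-reading task. Implements multi-trial short-window multivariate
    autoregressive (MVAR) modelling with Yule-Walker estimation and AIC order
    selection, the short-time direct directed transfer function (SdDTF),
    two-dimensional moving-average smoothing with FDR-controlled task-versus-
    baseline significance testing, group pooling across sessions, lexicality
    (word versus pseudoword) contrasts, and integrated flow-graph summaries.
    Ships a synthetic-cohort generator that simulates sessions from MVAR
    networks with known time-localized, condition-dependent directed couplings
    so that every pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
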
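Package: decaynet
Title: Simulation and Lifetime Prediction for Decaying Dynamic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo simulation of dynamic networks under persistent
    random attack, in which nodes fail internally (with a chance of
    permanent death), recover after a finite delay, and fail externally
    when the fraction of their active neighbours drops to a critical
    threshold. Provides network generators and edge-list input/output,
    mean-field theory for the stationary inactive fraction, spinodals and
    the analytic network lifetime, early-warning crash indicators on
    simulated trajectories, and forecasting of the remaining lifetime
    from a partial trajectory.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    jsonlite
Config/testthat/edition: 3
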
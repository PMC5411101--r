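Package: tfshare
Title: Stochastic Transcription under Shared Transcription-Factor Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic modelling of transcription when a limited pool of
    transcription factors (TFs) is shared between multiple identical promoter
    copies and competing (decoy) binding sites. Provides a Gillespie stochastic
    simulation engine with reproducible per-replicate random streams, an exact
    steady-state solver for the truncated chemical master equation over
    (occupancy, competitor, mRNA) states, closed-form telegraph-model moments and
    the variance-versus-mean master curves, a second-order moment-closure
    approximation, multimodality detection for mRNA copy-number distributions,
    exact two-promoter mRNA correlation, and figure-level parameter sweeps with a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
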
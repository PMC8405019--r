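Package: betahmm
Title: Beta-Observation Hidden Markov Models for Band-Limited Spectral Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments single-channel electrophysiological recordings (local field
    potentials or EEG) into discrete spectral states. Voltage traces are reduced to
    multitaper band power in canonical frequency bands, logistically scaled into the
    unit interval, and modelled with a hidden Markov model whose emissions are
    state- and band-specific beta distributions. Provides EM fitting over one or
    more independent recording sessions, Viterbi state decoding, Markov-chain
    duration statistics, analytic comparisons of state-specific beta distributions,
    and a simulation suite that validates estimation accuracy against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
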
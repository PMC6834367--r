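Package: riskybias
Title: Sequential-Bias and Neural-Population Analyses for a Rat Risky-Choice Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a rodent task in which animals choose
    between a cued guaranteed ('safe') reward and a cued probabilistic
    ('risky') reward whose side varies randomly over trials. Provides a
    task/agent simulator with plantable sequential biases, behavioral metrics
    (choice efficiency, risky win-stay and spatial win-stay/lose-switch biases
    with normal-approximation confidence intervals, bias-versus-probability
    slopes, laser-versus-control comparisons), a five-term logistic choice
    model and a four-parameter psychometric sigmoid, shuffle-corrected d-prime
    discriminability of single-unit firing rates, rank-restricted canonical
    polyadic (CP) decomposition of neuron x time x trial tensors with
    similarity-based rank selection and reward-triggered trial-factor
    averages, and cross-session unit matching from tetrode waveform templates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
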
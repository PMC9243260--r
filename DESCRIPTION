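Package: nacd
Title: Noise-Assisted Multivariate EMD Causal Decomposition for Bivariate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-dependency causality inference for bivariate time series.
    Decomposes a pair of signals jointly with noise-assisted multivariate
    empirical mode decomposition (NA-MEMD), summarizes each intrinsic mode
    function pair by Hilbert average frequency and phase difference, selects
    intrinsic causal components, removes the main component from each channel
    in turn, and quantifies the resulting disruption of phase coherence as
    absolute and relative causal strengths. Includes synthetic generators
    (white noise, coupled phase oscillators, noisy Lotka-Volterra
    predator-prey series) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
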
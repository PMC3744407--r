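Package: oscspike
Title: Spike-Train Statistics of Neurons Driven by Stochastic Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the perfect integrate-and-fire (PIF) neuron driven by
    harmonic (narrow-band) noise and broadband Ornstein-Uhlenbeck noise.
    Provides an exact-propagation stochastic simulator, closed-form weak-noise
    interspike-interval (ISI) statistics (density, coefficient of variation,
    skewness, serial correlation coefficients, correlation lag), non-parametric
    spike-train estimators (ISI summaries, serial correlations with segment
    error bars, Welch power spectra, stationarity filtering), and an inverse
    procedure that extracts the oscillator parameters (quality factor,
    frequency ratio, harmonic-noise amplitude, broadband-noise intensity) from
    a measured spike train by fitting the closed-form serial correlation
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
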
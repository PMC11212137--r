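Package: enantiopore
Title: Enantiomer Discrimination from Nanopore Current Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule peptide sensing with a
    wild-type aerolysin nanopore, built around the discrimination of
    peptide enantiomers (l- vs d-vasopressin) from resistive-pulse
    recordings. Simulates single-channel current traces with Poisson
    event arrivals, exponential dwell times and Gaussian blockade
    populations; detects blockade events by baseline thresholding and
    extracts the five standard event parameters (dwell time, mean,
    minimum and maximum blockade, in-event noise); fits blockade-level
    histograms with Gaussian and bi-Gaussian models, dwell-time and
    interevent-time distributions with exponentials; and classifies
    events as l- or d-peptide by correlation-matrix principal component
    analysis, Gaussian bands on the second principal component, and
    Monte Carlo label assignment, with confusion-matrix evaluation and
    mixture-ratio estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
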
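Package: snifflet
Title: Sniff-Warped Poisson Models of Olfactory Bulb Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing mitral/tufted-cell spike trains recorded in
    freely breathing animals, where respiration dynamics dominate response
    timing. Fits a Poisson generalized linear model in which a per-cell,
    per-odor log firing-rate pattern over normalized sniff time (a
    "snifflet") is temporally dilated on each sniff by the reciprocal of
    that sniff's inhalation duration. Estimation uses a Gaussian smoothness
    prior with squared-exponential covariance, hyperparameters chosen by
    Laplace-approximated evidence optimization, and Newton ascent to the
    posterior mode. Downstream statistics include first-significant-response
    polarity and latency, normalized population averages, concentration
    consistency categories, spike-count rate profiles, and optogenetic
    identification of light-responsive cells from peri-stimulus time
    histograms. A synthetic-data generator produces sniff trains, dilated
    inhomogeneous-Poisson spike trains, and cell populations with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
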
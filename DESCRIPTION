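Package: gmpda
Title: Gaussian Mixture Periodicity Detection for Event Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects one or more periodicities in binary event-onset time
    series by fitting Gaussian mixture models to the histogram of all
    forward inter-event intervals. Implements two generative schemes for
    periodic event data -- a Clock model with horizon-constant jitter and a
    Random Walk model whose interval variance grows linearly with interval
    order -- together with a uniform false-positive noise model, the
    mixture-curve detection algorithm (candidate extraction by comb
    folding, least-squares variance refinement, combinatorial period
    selection under an L1 loss), four spectral and folding baseline
    detectors, a simulation benchmark with a half-sigma accuracy
    criterion, and a reference-loss procedure for calling significant
    periodicities. Motivated by the analysis of periodic leg movements
    during sleep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
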
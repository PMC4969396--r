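Package: burstlab
Title: Burst Detection and Benchmarking for Neuronal Spike Trains
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects bursts in neuronal spike trains, such as those recorded
    with microelectrode arrays, using seven established deterministic
    detectors: MaxInterval, logISI histogram, cumulative moving average
    (CMA), Poisson surprise, rank surprise, robust Gaussian surprise, and
    the ISI rank threshold method. Includes a point-process simulator that
    generates spike trains with ground-truth burst labels (Poisson
    bursting, nonstationary bursting, and noisy bursting models, plus
    Poisson, gamma-ISI and inhomogeneous-Poisson nonbursting controls),
    and an evaluation harness computing true/false-positive spike
    fractions, sensitivity/specificity ROC sweeps, normalized Hamming
    distances between detectors, and burst summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
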
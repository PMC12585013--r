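Package: lnkit
Title: Linear-Nonlinear Cascade Analysis of State-Conditioned Visual Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse-correlation analysis of visual neuron spike
    trains recorded under white-noise stimulation in behaving animals:
    spike-triggered average (STA) estimation with per-bin significance against
    the N(0, 1/C) null, static nonlinearity estimation and before/after gain
    ratios, difference-of-Gaussians peak latency, spectral peak frequency,
    ON-OFF polarity and flash-response indices, 2-D Gaussian receptive-field
    fits, direction/orientation selectivity indices and functional typing.
    Includes behavioral-state segmentation (locomotion threshold, pupil-size
    tertiles, pupil-derivative states, eye-position stability) used to
    condition all estimators, an integrate-and-fire neuron simulator with
    Poisson spiking and refractoriness for gain/baseline parameter sweeps, a
    synthetic-data generator producing ground-truth linear-nonlinear Poisson
    sessions, and paired/group modulation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
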
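Package: dnflight
Title: Descending-Neuron Control of Drosophila Wingbeat Amplitude: Power
    Model, Optogenetic Dose-Response, and Bilateral Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studies of descending-neuron control of
    flight in tethered Drosophila. Implements the mass-specific aerodynamic
    power model for flapping flight (induced plus profile power, flapping-wing
    Reynolds number, drag-coefficient modes, and constant-power isolines in
    the wingbeat frequency-amplitude plane), trial segmentation and scoring of
    optogenetic activation experiments with per-fly and per-line aggregation
    and the cell-count dose-response regression, a bilateral two-photon
    imaging pipeline (cross-correlation registration, percentile ROI and
    background selection, ratiometric normalization, delta-F/F, behavior lag
    correction, bootstrap stimulus-triggered averages, tuning curves, and
    pixel-wise fluorescence-behavior correlation maps), and synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
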
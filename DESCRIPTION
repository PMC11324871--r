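Package: neuristor
Title: Simulation and Analysis of Thermal Neuristor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates two-dimensional arrays of thermally coupled vanadium
    dioxide (VO2) spiking oscillators ("thermal neuristors"). Each device is
    an RC circuit whose variable resistance follows a hysteretic
    insulator-to-metal transition; neighbouring devices are electrically
    isolated but exchange heat through the substrate. The package provides
    the scalar hysteresis model and its characteristic time scales,
    Euler-Maruyama integration of the coupled electro-thermal lattice
    dynamics with Gaussian thermal noise, spike detection and avalanche
    statistics (spatiotemporal coarse graining, Hoshen-Kopelman cluster
    labelling, logarithmically binned size histograms and power-law fits),
    phase-diagram sweeps over input voltage and thermal capacitance, and a
    reservoir-computing pipeline that encodes grayscale images as input
    voltages and trains a linear softmax readout on binary spike-train
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
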
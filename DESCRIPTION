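Package: cherenkovrt
Title: Cherenkov Light Emission in External Beam Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo simulation and analysis of Cherenkov light
    emitted in tissue during external beam radiotherapy of the larynx.
    Generates synthetic voxelized neck anatomies and water calibration
    phantoms with spectrally resolved optical properties, describes IMRT and
    VMAT deliveries as control-point sequences with a parametric 6 MV source,
    transports therapeutic X-rays (Klein-Nishina Compton plus photoelectric)
    and secondary electrons with continuous slowing down, generates Cherenkov
    photons along electron steps from the Frank-Tamm relation, propagates
    optical photons through heterogeneous tissue (Henyey-Greenstein
    scattering, Fresnel surface boundaries) to absorption or surface exit,
    and derives surface light maps, spectra, the tumor spot, origin-of-
    surface-light distributions and reduced-measurement-area comparisons,
    with monitor-unit calibration against a water phantom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    arrow,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
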
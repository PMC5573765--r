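Package: avflow
Title: Pulsatile Haemodynamics and Oxygen-Transport Analysis for Arterio-Venous Fistulae
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the non-CFD computational chain used in studies of
    pulsatile blood flow and oxygen transport in arterio-venous fistulae:
    synthesis and Womersley evaluation of Fourier-mode pulsatile inflow
    waveforms, a three-terminal RCR Windkessel lumped-parameter (0D) outlet
    network with iterative parameter calibration against reference pressure
    and flow targets, unsteadiness analysis of wall-shear-stress fields
    (ring averages, windowed power spectral densities, snapshot proper
    orthogonal decomposition with energy-based mode counting), time-averaged
    wall pathology mapping (Henry's-law oxygen concentrations, lumen-to-wall
    normal oxygen flux, threshold classification and area statistics),
    centreline geometry utilities (curvature, Dean number, sectional radius
    averaging), and seeded synthetic-data generators that stand in for a 3D
    CFD solver so every stage runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rhdf5,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
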
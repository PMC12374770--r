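Package: layertof
Title: Two-Layer Time-Domain Near-Infrared Spectroscopy Modelling and
    Tissue Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward and inverse modelling for time-domain near-infrared
    spectroscopy (TD-NIRS) of layered tissue. Implements the analytical
    time-domain and steady-state diffuse reflectance of a two-layer turbid
    medium (layered diffusion equation with extrapolated boundary), a
    layered time-resolved Monte Carlo simulator with per-layer partial
    pathlength recording and Beer-Lambert perturbation re-weighting,
    TCSPC transient calibration and rebinning, Levenberg-Marquardt
    estimation of layer optical properties from single-distance
    time-of-flight transients or multi-distance continuous-wave
    intensities, two-wavelength hemoglobin unmixing to a tissue
    oxygenation index (TOI), photon time-of-flight gating analysis of
    pulsatile signals, and reproducible simulation studies of deep-layer
    absorption recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
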
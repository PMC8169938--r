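Package: liebauflow
Title: Flow Quantification for Valveless (Liebau) Pump Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the output of valveless impedance (Liebau)
    pumps from tracer-particle video data. Provides closed-form physics
    calculators (Young modulus from a tensile test, Womersley number and
    oscillatory velocity profile, centerline-to-mean k_w correction,
    Moens-Korteweg pulse-wave speed, natural frequency, peristaltic
    reference output, glycerol-water viscosity, Poiseuille resistance
    scaling), a ground-truthed synthetic scene generator emulating 60
    frame/s clips of dark tracer particles under pulsatile flow, particle
    detection with nearest-neighbor linking and gap closing, Womersley
    corrected net-flowrate estimation with replicate variability, and
    sweep orchestration (frequency, viscosity, pincher position) with
    linear fits and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    grDevices,
    graphics,
    stats,
    tiff,
    png,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
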
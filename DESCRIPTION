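Package: lued
Title: Analysis Pipeline for Liquid-Phase MeV Ultrafast Electron Diffraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing and interpreting mega-electron-volt ultrafast
    electron diffraction (UED) data from thin liquid sheet jets. Covers
    relativistic electron kinematics, independent-atom-model scattering from
    explicit geometries and from pairwise radial distribution functions,
    azimuthal averaging of detector images, extraction of the modified
    scattering intensity sM(s) and real-space pair distribution function
    pdf(r), diffraction thermometry of liquid water via the first-peak
    calibration, thin-film interference and Beer-Lambert jet diagnostics,
    pump-probe instrument-response fitting of plasma-lensing traces, and a
    seeded synthetic-data generator that emulates the full instrument so
    every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
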
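Package: coilcal
Title: Magnetometer Array Calibration and Localization with Electromagnetic Coil Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calibrate magnetic field sensors (optically pumped and fluxgate
    magnetometers) for magnetoencephalography using the fields of large
    electromagnetic coils. Coil fields sampled at known positions are modelled
    with vector spherical harmonics; coil currents approximating homogeneous
    and first-order gradient fields are synthesized by pseudo-inversion;
    sensor gain, position and orientation are initialized from linear
    equations and refined by derivative-free least squares. Includes a
    Biot-Savart simulator of coils, sensor arrays and lock-in detected
    responses for validation, magnetic-dipole phantom localization, and
    rigid point-set alignment for error scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
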
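Package: irscatter
Title: Computational Occupational Dosimetry for Interventional Radiology
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the personal dose equivalent Hp(10) received by
    staff during interventional radiology procedures from machine-logged
    irradiation events and tracked operator positions, using Monte-Carlo
    photon transport of the scattered field. Per irradiation event a
    semi-empirical tungsten-anode spectrum is generated from the logged
    tube voltage and filtration, photons are transported through a
    patient phantom (BOMAB-type or prism) with next-event estimation of
    the scattered fluence spectrum at tracked operator positions, fluence
    is converted to Hp(10) with ICRU-slab conversion coefficients, and the
    result is normalised to the machine-reported kerma-area product or
    reference-point air kerma. Includes irradiation-event log and position
    trace I/O, room/C-arm geometry modelling with an optional ceiling
    shield, movement correction by event subdivision, procedure-level
    reporting with uncertainties, and a synthetic case generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
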
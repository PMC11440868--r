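Package: frickedose
Title: Internal Dosimetry of Positron-Emitting Radiotracers with the Fricke
    Chemical Dosimeter and Quantitative PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the absorbed radiation dose delivered by
    positron-emitting radiotracers (such as 18F-FDG) from Fricke
    ferrous-sulfate dosimetry combined with quantitative positron emission
    tomography (PET). Converts optical-density change of an irradiated
    Fricke solution into absorbed dose, simulates the ferrous-to-ferric
    oxidation kinetics of the dosimeter under constant or decaying
    dose-rate sources, handles radionuclide physical decay and cumulated
    (time-integrated) activity, fits forced-origin calibration lines
    relating dose, administered activity and time-integrated activity, and
    converts organ-level time-integrated activities into absorbed doses by
    both a conversion-factor method and the MIRD S-value formalism. A
    synthetic-data generator reproduces the statistical structure of every
    input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
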
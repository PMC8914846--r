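Package: thermocomfort
Title: Thermal Comfort Indices from Low-Cost Environmental Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes human thermal comfort from multi-channel environmental
    sensor time series of the kind produced by low-cost workplace monitoring
    devices: vapor pressure from air temperature and relative humidity,
    shortwave irradiance approximated from a light-level channel, five
    alternative estimates of mean radiant temperature (black globe
    thermometer, one-directional radiometry with spherical or standing-person
    weighting, brightness temperature, and air temperature), physiologically
    equivalent temperature (PET) via a three-node steady-state human energy
    balance, and classification into nine thermophysiological stress levels.
    Includes per-sensor linear calibration, evaluation statistics against a
    reference instrument (RMSE, MBE, MAE, MSE and light-level-binned
    differences), workplace stress-frequency summaries, a synthetic diurnal
    scenario generator with known ground truth, and a command-line interface.
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
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
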
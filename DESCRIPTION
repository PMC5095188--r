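Package: soarflight
Title: Thermalling Flight Mechanics from High-Frequency GPS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of thermal soaring flight from 1 Hz GPS tracks of
    large soaring birds. Detects full-circle thermalling segments, estimates
    the horizontal wind from the drift ("distortion") of successive circles,
    derives airspeed, circle radius, bank angle, lift acceleration and lift
    coefficient from banked-turn force balance, and quantifies how flight
    characteristics change with air density across altitude (equal-count
    elevation bins, density tail-group contrasts, and the regression of
    squared airspeed on inverse air density). Includes a synthetic flight
    simulator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
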
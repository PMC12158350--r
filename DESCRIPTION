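Package: ebnav
Title: Biomimetic Half-Adder Circuit Model for Egocentric-to-Allocentric
    Vector Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the Drosophila ellipsoid body-protocerebral bridge
    circuit as a bitwise vector-addition machine. Two-dimensional
    direction vectors are represented as sampled sinusoids (phasors),
    binarized with a range-number (thermometer) population encoder,
    summed lane-by-lane with a half-adder-like OR/AND activation, and
    decoded back to magnitude and angle from the peak position and the
    max-minus-min amplitude of the combined activity profile. Includes
    the egocentric-to-allocentric reference-frame transform (direct and
    four-axis projection paths), a seeded experiment harness with error
    and RMSE reporting, Gaussian-noise and multi-input scaling sweeps,
    complexity accounting for the network shape, CSV/JSON batch I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
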
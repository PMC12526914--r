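Package: kinasm
Title: Single-Molecule Kinetochore Assembly Kinetics from Two-Channel TIRFM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring kinetochore assembly kinetics on individual
    surface-tethered centromeric DNAs by colocalization single-molecule
    spectroscopy (CoSMoS). Simulates two-channel TIRFM fields with known
    ground truth, detects single-molecule spots and scores DNA-GFP
    colocalization over an incubation time course, verifies single-molecule
    character by photobleaching step counting, and fits sequential
    irreversible-step (Erlang-type) kinetic models with chi-squared model
    selection to report the plateau colocalization Cmax and the 30%-crossing
    time T30 per protein and condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
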
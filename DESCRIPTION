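Package: thrustwake
Title: Kinematics and Pressure-Field Analysis of Fish Swimming in Flapping-Foil Thrust Wakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing undulatory swimming in the thrust wake of a
    flapping foil: two-degree-of-freedom foil kinematics and nondimensional
    numbers (Strouhal, Reynolds), midline kinematics from digitised tracking
    tables (tail-beat frequency, joint angles, intersegmental phase lags, body
    wavelength, amplitude envelopes via principal components, foil-fish phase
    difference), planar pressure-field reconstruction from sequential velocity
    fields by median polling over eight families of boundary-seeded integration
    paths with solid-mask blocking, and the accompanying statistical
    comparisons (Welch t-tests, linear phase-distance fits). Includes seeded
    generators for synthetic traveling-wave swimmers and reverse Karman vortex
    streets so the full pipeline can be exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
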
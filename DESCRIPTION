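Package: fesprint
Title: Fluctuation-Enhanced Sensing Fingerprints from Sensor Noise Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fluctuation-enhanced sensing (FES) of odors with
    chemiresistive (Taguchi-type) gas sensors. Estimates the power density
    spectrum of pre-amplified sensor noise by Welch averaging, extracts
    binary fingerprints from the log-log slope structure of the spectrum
    (local chord slope below the global chord slope gives -1, otherwise +1)
    and ternary fingerprints relative to a reference-odor spectrum
    (-1/0/+1 for local slope below/equal/above the reference), and
    identifies unknowns by nearest fingerprint in a labelled library.
    Includes a seeded colored-noise simulator with piecewise power-law
    spectra so the whole sensing chain can be exercised without hardware,
    plus delimited-text and JSON readers/writers and a command-line tool.
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
    rlang,
    signal,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
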
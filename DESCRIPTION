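Package: muvi
Title: Multi UV-Absorbance Index Screening of Fulvic Acid Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for authenticating commercial fulvic acid products from
    their UV-Vis absorbance spectra. Implements the Multi UV-Absorbance
    Index (MUVI) workflow: reading and blank-correcting spectra, computing
    ten spectral indices (absorbance coefficients at 254-440 nm, exponential
    spectral slopes over 275-295 and 350-400 nm, the slope ratio, and the
    E2:E3 absorbance ratio), scoring percent error against the IHSS Suwannee
    River (SRFA) and Pahokee peat (PPFA) fulvic acid reference standards,
    and applying a dual-cutoff decision rule (raw absorbance at 254 nm and
    average percent error) to call a sample fulvic or non-fulvic. Includes
    a seeded synthetic-spectrum generator for testing the pipeline without
    instrument data, and a command-line interface for batch screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
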
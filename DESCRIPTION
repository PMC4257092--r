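Package: pmfspot
Title: Peptide Mass Fingerprinting and Proteoform Inference for 2-DE Spots
Version: 0.1.0
Authors@R:
    person("pmfspot", "maintainers", email = "pmfspot@example.org", role = c("aut", "cre"))
Description: In-silico tryptic digestion with missed cleavages and variable
    modifications, monoisotopic/average mass calculus, Bjellqvist isoelectric
    point computation, MALDI-TOF peak-list calibration and tolerance-based
    matching against theoretical fingerprints, coverage-based identification
    of two-dimensional electrophoresis spots, and inference of proteoform
    status (N-terminal truncation, des-Lys C-terminus, dimer) from the
    matched-peptide footprint. Includes a seeded synthetic-data generator
    (proteomes, proteoform families, gel spots, MALDI peak lists with a
    stated noise model) so the whole pipeline is testable offline, and a
    command-line entry point wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
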
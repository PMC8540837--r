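Package: peatmox
Title: Methanotroph Response Analysis for Closed-Bottle Peat Incubations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing methane-oxidizing bacterial (MOB) responses
    to CH4 concentration and temperature in closed-bottle incubations of
    Arctic peat soil and pure cultures. Covers the full computational chain:
    closed-vessel CH4 mass balance with Henry's-law gas/liquid partitioning
    and ideal-gas conversion, first-order oxidation-rate fitting with
    sampling-loss corrections and dry-weight or per-cell normalisation,
    absolute pmoA transcript quantification from qPCR dilution-series
    standard curves, pmoA amplicon post-processing (sliding-window quality
    filter, stop-codon/frame screen, length windows, best-alignment taxonomy,
    relative-abundance denoising, log normalisation), Dufrene-Legendre
    indicator-value analysis with a permutation null and the
    responding/unconditional bioindicator selection rules, and
    neighbor-joining phylogenetics with Jukes-Cantor distances and bootstrap
    support. Seeded synthetic-data generators with ground-truth records make
    every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
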
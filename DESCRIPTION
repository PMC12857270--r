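Package: roseg
Title: Discovery and Validation Analytics for ROSE-G RNA Thermometers
Version: 0.1.0
Authors@R:
    person("roseg", "maintainers", email = "roseg@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating ROSE-G class RNA
    thermometers in bacterial sequences. Implements a structural motif
    descriptor language (ordered single strands and nested helices with
    degenerate-nucleotide constraints), an exact window scanner with
    configurable base-pairing rules, candidate annotation against gene
    starts, motif classification, descriptor-implied secondary structure
    and mutation utilities, beta-galactosidase reporter statistics (Miller
    units, heat induction factors, replicate t tests), in-line probing
    band-intensity normalization, and a synthetic-data generator that
    plants motif instances in random genomes and simulates replicate assay
    and probing data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
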
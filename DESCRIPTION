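Package: panelqc
Title: Coverage and Sequence Quality Evaluation for Targeted NGS Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality evaluation of targeted next-generation sequencing data.
    Computes per-base depth-of-coverage, base-quality and mapping-quality
    profiles (COV, QCOV, MEDBQ, FLBQ, MEDMQ, FLMQ) over BED-defined target
    regions, reduces them to region-level summary metrics with configurable
    PASS/FLAG thresholds, accounts on-target and off-target reads per
    chromosome, and reports poor-quality intervals (low quality coverage) in
    simplified transcript c. coordinates. Includes a synthetic BAM fixture
    generator and an independent brute-force oracle used by the test suite,
    plus a command-line entry point driven by an INI configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
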
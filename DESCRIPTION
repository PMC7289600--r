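Package: fretquant
Title: Single-Cell Analysis of Compartment-Targeted FRET Biosensor Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell kinase activity from ratiometric
    FRET biosensor time-lapse experiments. Extracts background-corrected
    acceptor/donor (Y/C) ratio traces from two-channel image stacks, normalizes
    them to the pre-stimulus baseline, and computes per-cell response metrics
    including the maximum fractional response, time to half-maximal response,
    inhibitor-induced slope changes, and the sustained activity metric at
    40 minutes (SAM40) that separates sustained from transient responses.
    Includes FDR-controlled robust outlier flagging, an iterative Pearson
    correlation filter for biosensor expression artifacts, kymograph-based
    membrane protrusion quantification with cell morphology measures, condition
    summaries and comparisons, and seeded synthetic-data generators (traces,
    two-channel stacks, protrusion mask movies) so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
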
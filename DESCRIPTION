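Package: mzqckit
Title: Toolkit for the mzQC Mass Spectrometry Quality-Control Exchange Format
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write, and validate quality-control reports in the HUPO-PSI
    mzQC JSON exchange format for mass spectrometry. Provides a typed document
    model with construction-time invariant checks, faithful JSON
    (de)serialization, syntactic validation with structured findings, semantic
    validation against a controlled vocabulary parsed from OBO, computation of
    run-level QC metrics (ion chromatograms, injection-time statistics,
    precursor mass-error distributions, missed-cleavage counts,
    identification counts) from in-memory runs and peptide-spectrum-match
    tables, merging of partial reports into a single document, and a
    percentile-rank clustered heatmap report. A seeded synthetic-experiment
    generator with exact ground truth makes every step testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pheatmap,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
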
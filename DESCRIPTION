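Package: mitorepair
Title: Analysis of Mitotic DNA Double-Strand-Break Repair Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the readouts of mitotic DNA
    double-strand-break repair experiments: classification of
    CRISPR-cut amplicon repair products into deletion and
    microhomology calls with exclusion filters, a sequence-level model
    of an extrachromosomal microhomology end-joining substrate with
    delta-delta-Ct repair-efficiency quantification, robust Z-score
    analysis of plate-based siRNA screens with Tukey median-polish
    positional correction and replicate-aware hit calling, and
    steady-state one-site binding-isotherm fitting for biosensor data.
    Includes seeded synthetic-data generators that emulate each assay
    so every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
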
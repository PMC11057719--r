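Package: drwhite
Title: Trace Decomposition and Repair-Pathway Analysis for DR-white
    Double-Strand Break Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies DNA double-strand break repair outcomes from the
    Drosophila DR-white reporter assay. Decomposes Sanger chromatogram
    signals at an I-SceI-induced break site into a normalized indel
    spectrum by non-negative least squares against indel-shifted copies
    of a control trace, classifies spectra into homologous recombination
    (the diagnostic 23-bp deletion restoring the SacI site), NHEJ with
    indels, and no-DSB outcomes, scores premeiotic germline repair events
    from progeny eye and body-color phenotypes, and compares groups with
    Welch t, Wilcoxon signed-rank, factorial ANOVA and Tukey HSD tests.
    Ships a fully seeded synthetic-data generator (reference constructs,
    chromatogram mixtures with known truth, tissue cohorts, multinomial
    progeny tables) so every stage is verifiable without raw traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    car,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    BiocGenerics
Config/testthat/edition: 3
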
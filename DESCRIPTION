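Package: circascreen
Title: Cross-Tissue Screening for Amplitude Regulators of the Circadian
    Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects rhythmic gene expression across multi-tissue
    time-course datasets and screens for genes whose relative amplitude or
    mean expression tracks each tissue's fraction of cycling genes.
    Rhythmicity calls combine harmonic (cosinor) regression, a Lomb-Scargle
    periodogram and a JTK-style rank test with an exact Kendall-S null,
    integrated by Fisher's method with Benjamini-Hochberg control per tissue.
    The screen correlates per-gene features against per-tissue cycling
    percentages, ranks genes by averaged Fisher Z across platforms, and
    intersects significant hits between platforms. Also included: exact
    p-value position weight matrix scanning of promoter windows, singular
    value decomposition of gene-by-tissue feature matrices, and a synthetic
    multi-tissue circadian expression generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
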
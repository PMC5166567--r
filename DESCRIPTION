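Package: mupquant
Title: Proteoform-Specific Label-Free Quantification for Homologous Protein Families
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free, proteoform-resolved quantification for highly
    homologous protein families, modelled on the major urinary proteins
    (MUPs) of the house mouse. Provides in-silico tryptic digestion and
    proteotypic-peptide mapping under alternative database contexts,
    MS1 (precursor) and MS2 (fragment/SWATH-style) intensity roll-up to
    proteoform level, three normalization strategies (none, total area
    sums, manual scale factors from protein concentration), paired
    differential-expression testing with Bonferroni-Dunn correction and
    a two-fold significance filter, detection-frequency classification,
    MS1/MS2 fold-change concordance, and relative-composition estimation
    by a unique-peptide-normalized 100 percent method. Includes a seeded
    synthetic-data generator that emulates a homologous proteoform
    family, a paired two-time-point study design and peptide-level
    quantification matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
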
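Package: sipef
Title: Transcriptome Stable-Isotope Probing: Gradient Profiles, Read
    Accounting and Enrichment Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for total RNA stable-isotope probing (SIP)
    metatranscriptomics at the post-classification level: quantitative
    buoyant-density gradient profiles, selection of heavy and light
    sequencing pools under a minimum-RNA constraint, per-library read-class
    and GC accounting, taxon and transcript enrichment factors
    (EF = heavy13C/light13C - heavy12C/light12C) at any taxonomic or
    functional depth, and alpha-diversity summaries. Ships a synthetic
    SIP-experiment generator (community, isopycnic fractionation, qPCR
    profiles, pooled multinomial read sampling, optional GC-lowering
    amplification bias) with known ground truth, so every pipeline stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
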
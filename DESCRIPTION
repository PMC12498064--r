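Package: chromarch
Title: Comparative Chromatin Architecture and Regulatory Genomics Between Two Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative three-dimensional genome and
    regulatory-genomics analysis between two tissues or conditions. Implements
    Hi-C contact-map balancing by iterative correction, distance-decay (P(s))
    profiles, LOWESS z-score difference matrices, A/B compartment calling with
    gene-density orientation and switch classification (A2A/A2B/B2A/B2B),
    saddle analysis with corner-ratio compartment strength, insulation-score
    TAD boundary detection and TAD-change classification (merge/split/stable/
    rearrangement), multi-resolution donut-background loop calling with
    cross-condition comparison and aggregate peak analysis, open-chromatin
    region local/distal classification, differential accessibility and
    expression gates, histone-mark four-case enhancer classification, and
    distal-OCR / enhancer to gene linking through loop anchors. Ships a
    synthetic paired-condition multi-omic data generator with fully known
    planted truth so every stage has a recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
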
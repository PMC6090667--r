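Package: umisrna
Title: UMI-Aware Small RNA Sequencing with SPRI Bead Size-Selection Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for gel-free small RNA sequencing workflows. Plans
    SPRI (solid-phase reversible immobilization) bead size selections for
    nucleic acids shorter than 100 nt from a binding-efficiency calibration
    table and the PEG/isopropanol mixing equation; simulates barcoded,
    UMI-labelled small RNA libraries with ligation and PCR amplification
    bias and known ground truth; demultiplexes, adapter-trims and
    UMI-collapses reads; quantifies inserts against mature miRNA, 21U and
    genome references by exact matching with hit-count gates; and provides
    replicate-dispersion, normalization, negative-binomial differential
    expression, UMI label-collision correction and adapter-bias statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, Preprocessing, DifferentialExpression
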
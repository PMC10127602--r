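Package: regulonkit
Title: Reporter Kinetics, qRT-PCR Quotients and TSS Calling for Bacterial
    Promoter Induction Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis toolkit for studies of bacterial promoter
    induction by two-component regulatory systems. Converts plate-reader and
    tube-assay absorbances into beta-galactosidase activities, fits linear
    lag and quadratic models to reporter induction time courses and compares
    slopes between strains, computes reference-gene-normalized qRT-PCR
    induction quotients, and calls transcription start sites from stranded
    Cappable-seq-style 5'-read-start count tracks using reads-per-million
    normalization with cutoff, clustering, replicate-reproducibility and
    score rules, including strand-aware promoter sequence extraction.
    Synthetic-data generators emulate every input so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
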
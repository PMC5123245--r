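Package: MitoVarAnnot
Title: Structure-Aware Annotation of Human Mitochondrial DNA Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Annotates human mitochondrial DNA variants with transfer-RNA
    structural context (Sprinzl position numbering, tRNA type, cloverleaf
    domain, mature nucleotide after post-transcriptional modification, and
    tertiary-folding involvement), normalizes literature pathogenicity
    scores for tRNA and rRNA variants against damaging/neutral thresholds,
    exhaustively enumerates and classifies the single-nucleotide mutational
    space of the thirteen protein-coding genes under the vertebrate
    mitochondrial genetic code, and exports annotated variant tables and
    GFF3 genome-browser tracks. Ships a curated reference bundle on rCRS
    coordinates and a deterministic synthetic-fixture generator so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
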
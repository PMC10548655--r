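Package: agmetric
Title: Coverage-Aware Gene-Level Genome Assembly Quality and Assembler
    Parameter Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes AG ("accurately assembled genes"), a genome assembly
    quality metric that counts genes in single-copy BUSCO orthogroups plus
    genes in true multicopy orthogroups, where multicopy orthogroups are
    split into true (paralogues, full read coverage) and false (uncollapsed
    haplotypes, roughly half coverage) using median exonic read depth and a
    (3/4) x Cov(S) threshold. Includes parsers for PAF alignments, HMMER3
    text profiles, BED exon models, blast tabular hits and BUSCO-style
    cutoff tables; conservation ranking of orthogroups by mean positional
    relative entropy; a golden-section search that tunes a single assembler
    parameter (Hifiasm -s, or Flye max_divergence on a log10 scale) to
    maximize AG; command constructors for Hifiasm and Flye; and a seeded
    mock assembler plus synthetic fixture generator so the whole
    optimization loop runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
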
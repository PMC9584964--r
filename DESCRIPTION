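Package: conmine
Title: Mining Coniine Biosynthesis Pathway Candidates from a De Novo
    Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in silico pipeline for identifying candidate enzymes of the
    coniine biosynthesis pathway of poison hemlock (Conium maculatum L.) from
    an annotated de novo transcriptome. Integrates homology, protein-domain
    and classifier annotation evidence under fixed thresholds, removes
    non-plant contaminant transcripts by best-hit taxonomy, normalizes
    fragment counts (FPKM and trimmed mean of M-values), calls per-organ
    presence and organ set overlaps, runs preranked gene set enrichment with a
    permutation null, applies declarative per-enzyme filter cascades
    (protein-family seeds, co-expression, molecular-weight window, cofactor
    and EC-class filters), and quantifies relative expression from qPCR Ct
    tables by the comparative Ct method with propagated standard deviations.
    A synthetic-transcriptome generator with planted ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
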
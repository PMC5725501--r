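Package: boxascan
Title: Comparative-Genomics Screen for BoxA Antitermination Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scans bacterial genomes for the degenerate BoxA consensus
    GYTCTTTAANA on both strands, retains matches falling in the 50-nt
    window immediately upstream of annotated gene starts, aggregates the
    functions of downstream genes at genus level to control for uneven
    genome sampling, scores per-column conservation of upstream-region
    alignments against a reference sequence, and flags pyrimidine-rich,
    G-poor segments characteristic of Rho-utilization (Rut) sites. A
    synthetic-genome generator with planted ground truth makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
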
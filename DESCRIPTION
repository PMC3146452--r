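Package: mirprom
Title: Promoter Regulatory Analysis of Differentially Expressed miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for regulatory analysis of microRNA promoters in
    myeloid cells. Screens qPCR delta-Ct profiles for miRNAs differentially
    expressed between monocytes and dendritic cells (one-way ANOVA with
    Benjamini-Hochberg FDR control and Tukey post-hoc comparisons), scans
    2 kb upstream promoter regions for transcription-factor binding sites
    with a likelihood-ratio position-weight-matrix model, scores motif
    over-representation with a subset-averaged likelihood ratio and a
    randomization p-value, attaches per-base conservation scores to
    predicted sites with percentile filtering and a random-block null,
    tests shared-motif enrichment of promoter sets against random draws
    from a promoter pool, and integrates motif sharing with
    transcription-factor expression calls. A synthetic-data module
    generates every input with known ground truth so all stages are
    testable without genome-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
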
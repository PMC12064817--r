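Package: lncscout
Title: Discovery and Scoring of Novel Intergenic lncRNAs from Multi-Sample RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate intergenic long noncoding RNAs from a cohort of
    aligned RNA-seq samples. The genome is scanned in sliding windows of
    RPM-normalized coverage, windows with outlier expression across the cohort
    are selected, windows overlapping annotated genes are removed, and the
    surviving regions are expanded to gene-body structures using spliced
    alignments. Each candidate is then scored on promoter composition and
    core-promoter motifs (TATA, Initiator, DPE), poly(A) signal and T-rich
    3' region, open reading frame coverage, and splice-junction-supported
    exon structure, and ranked by the summed score. A deterministic synthetic
    cohort generator with planted transcripts is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
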
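Package: junctionfilter
Title: Self-Training Splice Junction Filtering for Spliced RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and removes false splice junctions from spliced RNA-seq
    alignments. All distinct junctions are extracted from reference-skip CIGAR
    operations in SAM/BAM input, quantified with alignment-derived metrics
    (read-support classes, Shannon entropy of anchor offsets, anchor coverage
    deviations, maximal overhang, mismatch-truncated MaxMMES) and genome-derived
    metrics (donor/acceptor dinucleotides, repeat hamming scores, intron-size
    score, position weight matrix and splicing-signal scores). A per-dataset
    random-forest classifier is self-trained from rule-derived positive and
    negative junction sets balanced with synthetic minority oversampling, and
    used to score and filter the full junction set. A companion toolkit handles
    junction file formats (tab, BED6/BED12, GFF3 intron hints, mapper splice-site
    hints), set algebra with per-sample markup, reference comparison into four
    annotation-support classes, and recall/precision evaluation. A synthetic
    fixture generator produces genomes, annotations and alignments with planted
    genuine and characteristically false junctions for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
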
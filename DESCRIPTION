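Package: oncocodon
Title: Transcriptome-Weighted Codon and Codon-Pair Usage Analysis of
    Tumor and Normal Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes transcriptome-weighted codon and codon-pair usage
    from coding sequences and gene-level expression, and compares tumor
    against matched normal transcriptomes. Provides cohort assembly with
    sample-selection filters and matched tumor-normal pairing, usage
    normalization (codons per thousand, codon pairs per million),
    relative synonymous codon usage (RSCU) and per-patient RSCU shifts,
    divergence metrics (mean squared error, signed percent differences,
    Euclidean distance matrices, codon-pair percentile ranks and
    observed/expected ratios), regression and paired Wilcoxon screens
    with Bonferroni control, principal component analysis and
    hierarchical clustering of usage vectors, Kaplan-Meier survival
    stratification by usage divergence, and a synthetic cohort generator
    with planted usage shifts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
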
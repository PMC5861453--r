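Package: foreignscan
Title: Transcription-Unit Refinement and Compositional Signatures of
    Non-Native Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream transcriptome-response analysis for prokaryotic and
    archaeal RNA-seq studies: refinement of a transcription-unit (operon) map
    against mapped primary transcription start sites (5'-end adjustment,
    internal-TSS shortening, orphan-gene unit creation), strand-aware promoter
    window extraction, genome-wide synonymous codon usage with per-gene
    rare-codon frequency and AT content, and contingency-table association of
    composition, replicon and functional category with the direction of
    differential expression (two-sided Fisher exact tests with Bonferroni
    correction, quartile contrasts, Wilcoxon abundance contrasts). Includes a
    fully synthetic multi-replicon genome generator with native and foreign
    codon-usage regimes so the whole pipeline is testable end to end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
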
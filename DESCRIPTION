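Package: chromcode
Title: Differential Chromatin Blocks and a Predictive Chromatin Code for
    Repressor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of chromatin changes induced by a
    transcriptional repressor. Detects differential chromatin blocks from
    replicated, binned ChIP-seq coverage with a sliding-window negative
    binomial test, annotates blocks and cofactor peaks to genes by nearest
    transcription start site, computes hypergeometric co-occurrence
    statistics between region sets, builds composite profiles and heatmap
    matrices around affected regions, assembles a 41-feature per-gene table
    combining chromatin blocks, repressor/cofactor peaks and expression,
    and runs an iterated feature-selection / classification / majority-vote
    procedure to predict which genes are transcriptionally repressed. A
    synthetic-cohort generator with planted ground truth makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    e1071,
    class,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
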
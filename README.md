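# chromcode

Genome-wide analysis of chromatin changes induced by a transcriptional
repressor, for researchers studying how long-range repressors (HES-family
proteins like Drosophila Hairy, with their Groucho/CtBP cofactors) remodel
chromatin and silence genes. The package answers two linked questions:

1. **Where does chromatin change?** A sliding-window negative-binomial
   detector finds *differential blocks* — merged runs of windows where a
   histone mark or Pol II differs between wild-type and repressor-induced
   conditions — and annotates them to genes, genomic context, and repressor
   binding.
2. **Which changes predict repression?** A per-gene table of 41 chromatin
   features (block counts/widths/magnitudes/distances for 6 histone marks +
   Pol II, peak features for 3 binding factors, wild-type expression) feeds
   an iterated feature-selection / classification / majority-vote procedure
   — the "chromatin code" — that predicts whether a gene is
   transcriptionally repressed.

## The core statistics

For window counts $m_1, m_2$ (replicate means per condition, normalized to
10M tags), the detector tests equality of means with a Wald statistic on
log means under a negative-binomial model with method-of-moments common
dispersion $\hat\phi$:

$$z = \frac{\log(m_2+c) - \log(m_1+c)}
{\sqrt{(1/(\bar m + c) + \hat\phi)(1/n_1 + 1/n_2)}}, \qquad
\log_2\mathrm{FC} = \log_2\frac{m_2+c}{m_1+c},\ c = 1.$$

Windows with $p < 0.05$ and $|\log_2\mathrm{FC}| > 0.4$ merge into
direction-consistent blocks with boundary refinement to the bin grid.
Co-occurrence between region sets is a signed natural-log hypergeometric
tail (negative = enrichment, positive = divergence), with "overlap" meaning
at least 1 shared bp. The classifier grid crosses four feature selectors
(information gain, symmetrical uncertainty, chi-square, ReliefF) with four
classifiers (random forest, naive Bayes, kNN, linear SVM) over 50 stratified
10-fold cross-validation iterations; per-gene calls aggregate by strict
majority vote.

Because no raw data accompany the design, a seeded synthetic-cohort
generator (`generate_cohort`) produces the full input set — replicated NB
coverage tracks with planted differential blocks, enriched peak sets, an
expression table with a 241/146/196 repressed/activated/unaffected cohort —
plus ground truth for every planted object.

## Worked example

```r
library(chromcode)
cfg <- cohort_config(seed = 42, n_chroms = 1, chrom_length = 6e5, n_genes = 60,
                     class_counts = c(repressed = 25, activated = 15, unaffected = 20))
cohort <- generate_cohort(cfg)
blocks <- call_blocks_all_marks(cohort)
h4 <- blocks$H4Ac
cat("H4Ac blocks:", nrow(h4), "| decreases:", sum(h4$direction == "decrease"),
    "| mean width:", round(mean(interval_width(h4))), "bp\n")
#> H4Ac blocks: 31 | decreases: 27 | mean width: 2371 bp

ann <- annotate_regions(h4, cohort$genes)
table(ann$context)
#>       exon intergenic     intron   promoter
#>          5          4          9         13

mean(link_hairy_bound(h4, cohort$peaks$Hairy, cohort$genes))
#> [1] 0.48

marks <- c("H4Ac","H3K27Ac","H3K4me1","H3K4me3","H3K36me3","H3K9me3","PolII")
tab <- build_feature_table(blocks[marks], cohort$peaks, cohort$expression, cohort$genes)
fit <- run_chromatin_code(tab, ml_config(selectors = "info_gain",
                                         classifiers = "random_forest",
                                         n_folds = 5, n_iterations = 10,
                                         base_seed = 42))
fit
#> chromcode_fit: 1 selector x classifier combination(s), 60 genes
#>   selector    classifier overall repressed nonrepressed baseline_overall
#>  info_gain random_forest     100       100          100               58
#>  baseline_repressed
#>                41.7
```

Reading the output: most H4Ac blocks are decreases (the planted
deacetylation signature), they sit promoter-proximal on ~2.4-kb domains,
about half land on repressor-bound genes, and on this small, cleanly
separable cohort the random forest calls every gene correctly against a 58%
majority-class baseline. `run_pipeline(pipeline_config())` wires all stages
end to end and writes every intermediate (bedGraph/BED/GFF3/TSV plus a
manifest with file digests).

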
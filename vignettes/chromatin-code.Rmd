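---
title: "Detecting differential chromatin blocks and predicting repression targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential chromatin blocks and predicting repression targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`chromcode` analyzes what happens to chromatin when a single transcriptional
repressor is induced genome-wide: where histone marks and RNA polymerase II
occupancy change, how those changes relate to repressor and cofactor binding,
and — the central question — which combination of chromatin features best
predicts that a gene is actually transcriptionally silenced rather than merely
visited by the repressor ("errant targeting": biochemically real chromatin
change with no expression consequence).

The pipeline has five computational stages, each usable on its own:

1. **Track handling** (`read_tracks`, `normalize_track`): binned replicate
   coverage, library-size normalized to ten million tags per replicate.
2. **Differential block detection** (`scan_windows`, `merge_and_filter`):
   a sliding-window negative-binomial test, then merging of significant
   same-direction windows into blocks.
3. **Annotation** (`nearest_tss`, `classify_context`, `link_hairy_bound`):
   blocks and peaks are attached to genes and genomic context.
4. **Set statistics and profiles** (`cooccurrence_matrix`,
   `composite_profile`, `compare_block_widths`): hypergeometric
   co-occurrence between mark/direction categories, composite signal views,
   width-distribution comparisons.
5. **The chromatin code** (`build_feature_table`, `run_chromatin_code`):
   a 41-feature per-gene table feeding an iterated feature-selection /
   classification / majority-vote procedure.

A seeded synthetic-cohort generator (`generate_cohort`) with planted ground
truth makes the whole chain testable end to end without any external data.

# The window test

For each sliding window (default 1 kb, 500 bp step) the detector compares
replicate-mean normalized counts between conditions. Counts are modeled as
negative binomial with a single common dispersion $\phi$ shared across the
genome, estimated by the method of moments: with per-window replicate mean
$m_w$ and variance $v_w$,
$$\hat\phi = \frac{\sum_w (v_w - m_w)}{\sum_w m_w^2},$$
pooled over both conditions and clamped at zero. The test statistic is a
two-sided Wald contrast of log means,
$$z = \frac{\log(m_2 + c) - \log(m_1 + c)}
{\sqrt{\left(\frac{1}{\bar m + c} + \hat\phi\right)
\left(\frac{1}{n_1} + \frac{1}{n_2}\right)}},$$
with pseudocount $c = 1$ and $\bar m$ the pooled mean. Evaluating the
variance at the pooled (null) mean rather than at each group's own mean makes
the statistic exactly antisymmetric under condition swap, so the detector's
symmetry property holds to machine precision; on 10,000-window null
simulations at the generator's default depth the empirical type-I rate is
within about half a percentage point of the nominal 0.05. With a single
replicate in both conditions the dispersion is not estimable and the test
degrades to Poisson ($\phi = 0$) with a warning.

Windows pass when $p < 0.05$ and $|\log_2 \mathrm{FC}| > 0.4$; touching or
overlapping same-direction windows merge into a block whose fold change is
the width-weighted mean of its members and whose p-value is the member
minimum. No multiplicity correction is applied on top of the stated filter —
the fold-change threshold, not the p-value, is what controls the block count
in practice at these depths.

## Boundary refinement

A merged run of 1-kb windows overshoots the true extent of a differential
region by up to half a window on each side: an edge window needs only ~40%
of its span inside the region to pass. `merge_and_filter` therefore trims
each merged block to the outermost 25-bp bins whose 250-bp-smoothed log2
fold change still passes the threshold in the block's direction. On planted
blocks this recovers boundaries to within roughly one smoothing half-window
(planted 2.5-kb blocks are recovered at ~2.46 kb mean width, Jaccard
typically > 0.9), where the raw window union would run ~30% wide. The
smoothing width trades boundary bias against noise sensitivity; 250 bp (ten
bins) keeps the per-side placement error near $\pm 100$ bp at the default
coverage while making spurious single-bin excursions rare.

# Annotation conventions

* Regions are assigned to the gene with the **nearest TSS measured from the
  region midpoint**; ties break to the lexicographically smaller gene id.
  Distances are strand-oriented (negative upstream).
* The promoter window is $[\mathrm{TSS}-1000, \mathrm{TSS}+100)$ in
  strand-oriented coordinates, a conventional promoter-proximal definition;
  context precedence is promoter > exon > intron > intergenic, so context
  categories partition any region set.
* A block counts as repressor-bound iff its nearest gene has at least one
  repressor peak assigned (also by nearest TSS).
* For Pol II change classification the gene body starts 250 bp downstream
  of the TSS, separating promoter-proximal (paused) signal from elongation
  signal; genes are classed as promoter-only, body-only, both, or none by
  which compartments overlap a Pol II decrease-block.

# Overlap statistics

Two regions overlap if they share at least one base (half-open
coordinates, so `[100,200)` and `[199,300)` overlap while `[100,200)` and
`[200,300)` do not). Significance is a signed natural-log hypergeometric
tail: non-positive for enrichment (observed at or above expectation),
non-negative for divergence. For gene sets the universe is the gene cohort.
For region sets no canonical universe exists; the package models the genome
as a row of placement slots, $N = \mathrm{genome\ length} / \mathrm{mean\
pooled\ region\ width}$, a stated convention chosen for reproducibility.
Because region-level p-values depend on that convention, they are
comparative quantities (which pairs co-occur more than others), not
portable significance claims.

# The synthetic cohort

The generator emulates the statistical structure the analysis assumes, not
raw sequencing. Defaults, chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| genes | 583 = 241/146/196 | repressed / activated / unaffected cohort |
| genome | 4 × 1.2 Mb | one private territory per gene (~8 kb) |
| bins | 25 bp | pre-binned counts, no read placement |
| background | NB(mean 5, size 10) per bin | ~1M tags/replicate before normalization |
| replicates | 3 per condition | |
| planted effect | \|log2 FC\| = 1.5 | multiplies the NB mean inside the block |
| H4Ac width | gamma(shape 4, mean 2500 bp) | other marks 1.5–2 kb means |
| P(blocks \| repressed) | 0.8 | carrier genes plant per-mark with 0.3–0.9 |
| P(blocks \| nonrepressed) | 0.3 | the errant-targeting fraction |
| peak enrichment | 0.8 vs 0.15 background | repressor/cofactor peaks near the TSS |

Effects multiply the negative-binomial *mean* rather than the sampled
counts, so replicate noise stays NB-distributed — the detector's model is
the generator's model. Block directions follow mark biology: active marks
and Pol II decrease on affected genes, the repressive H3K9me3 mark
increases; an H3 density control is simulated with no planted effects. A
background rate (0.05/gene/mark) of unrelated random-direction blocks keeps
the increase categories populated. Expression fold changes are drawn so
class labels and the differential-expression filter (p < 0.05, fold change
> 2, reciprocal for repression) agree by construction.

What the generator does **not** emulate: peak-shaped background (background
is flat), mappability and GC structure, fragment-length effects,
correlated replicate artifacts, and any quantitative coupling between block
magnitude and expression fold change (none is published). Passing tests
therefore demonstrate the machinery is correct under the assumed model, not
that real embryo data would reach the same accuracy.

All draws derive from one cohort seed via fixed stage offsets, so a cohort
is reproducible file-for-file and any stage can be regenerated alone.

# The 41-feature table and the classifier grid

Per gene: four aggregate features for each of the seven differential
datasets (block count, total block width, maximum |log2 FC|, minimum
|TSS distance|), four for each of the three binding factors (peak count,
total width, maximum height, minimum |TSS distance|), plus wild-type
expression — $4 \times 7 + 4 \times 3 + 1 = 41$. The four aggregation rules
are deliberately simple monotone summaries ("range of blocks" is read as
total width). Genes without a linked region in a dataset get zero
counts/widths/magnitudes and a 100-kb distance sentinel — finite and
rankable, and far beyond any plausible regulatory distance on these
territories.

The classification procedure mirrors ensemble practice: per iteration, a
stratified 10-fold split; per fold, features are ranked **on the training
90% only** (information gain, symmetrical uncertainty, chi-square — all on
10-bin equal-frequency discretizations — or ReliefF with 10 neighbors over
all training instances), the top 20 kept, and one of four classifiers fitted
(random forest, 100 trees; Gaussian naive Bayes with a variance floor;
5-nearest-neighbors on standardized features; linear SVM, cost 1). Fifty
iterations are aggregated per gene by majority vote: repressed iff strictly
more than 50% of votes, a 25/25 tie falling to the nonrepressed majority
class. Iteration seeds are `base_seed + iteration`; classifier seeds derive
from (iteration, fold) only, so selectors that pick identical top-20 sets
provably share a fit, which the grid runner memoises.

On default cohorts the random-forest branch reaches ~95% aggregate accuracy
against a 58% majority baseline — higher than a real cohort would allow,
because the planted class structure is cleaner than biology; the benchmark
checks the procedure clears the reported ~75% level, not that it matches it.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere; GFF3 shifts on read/write.
* TSS of a minus-strand gene is `end - 1` (the last covered base).
* Window/step must align to the track bin grid; the detector refuses
  otherwise rather than resampling silently.
* The hypergeometric tail is computed in log space (`phyper(log.p=TRUE)`);
  no underflow for universes to at least 1e6.
* `evaluate` truncates the majority baseline to an integer for display
  (58 for 241/342), as success-rate figures conventionally do.
* Degenerate inputs fail loudly: empty region lists for profiles, zero-total
  replicates for normalization, constant labels for ranking, fewer than two
  peaks for a correlation.

# Problem sizes

The bundled tests run the full-size benchmark (five default 4.8-Mb cohorts,
583 genes, the complete 50-iteration random-forest grid under all four
selectors) plus small fixtures for every operation; the end-to-end pipeline
test uses a reduced cohort (60 genes, one 0.6-Mb chromosome, 3 iterations)
since it exercises wiring, not statistical power. `scripts/acceptance.R`
regenerates the benchmark from scratch.

# Limitations

* The detector tests replicate means with a genome-wide common dispersion;
  per-window dispersion shrinkage (as dedicated count-based DE frameworks
  do) would be preferable at very low replicate numbers.
* Region-level overlap p-values depend on the stated universe convention.
* The block-width comparison uses the two-sample Kolmogorov–Smirnov test;
  widths quantized to the bin grid make the p-value asymptotic, not exact.
* The ML stage reports cross-validated majority-vote accuracy only; it does
  not calibrate probabilities or handle class weights beyond
  stratification.
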
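# Shared fixtures: tiny hand-built tracks/genes and a cache of full-default
# cohorts so the expensive benchmark cohorts are generated once per session.

# One-chromosome track from per-replicate count vectors.
make_track <- function(..., mark = "H4Ac", condition = "wt", bin = 25,
                       chrom = "chr1") {
  reps <- list(...)
  len <- length(reps[[1]]) * bin
  counts <- lapply(reps, function(v) setNames(list(as.numeric(v)), chrom))
  signal_track(mark, condition, bin, setNames(len, chrom), counts)
}

# Constant-mean NB track with an optional multiplicative effect window.
nb_track <- function(nbins, mu = 5, size = 10, n_rep = 3, effect = NULL,
                     mark = "H4Ac", condition = "wt", bin = 25,
                     chrom = "chr1") {
  muv <- rep(mu, nbins)
  if (!is.null(effect)) {
    idx <- (effect$start / bin + 1):(effect$end / bin)
    muv[idx] <- muv[idx] * effect$factor
  }
  reps <- lapply(seq_len(n_rep), function(r)
    setNames(list(as.numeric(rnbinom(nbins, mu = muv, size = size))), chrom))
  signal_track(mark, condition, bin, setNames(nbins * bin, chrom), reps)
}

# Two genes on one chromosome with exons, for annotation tests.
two_gene_set <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(1000, 9000), end = c(4000, 12000),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    start = c(1000, 3000, 9500), end = c(1500, 3600, 10500),
    stringsAsFactors = FALSE)
  gene_set(genes, exons)
}

# Session cache for default-condition cohorts and their called blocks.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed) {
  key <- paste0("cohort_", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cohort_config(seed = seed))
  .cohort_cache[[key]]
}

cached_blocks <- function(seed) {
  key <- paste0("blocks_", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- call_blocks_all_marks(cached_cohort(seed))
  .cohort_cache[[key]]
}

# Small separable feature table for classifier tests: feature f1 carries the
# label, f2..f4 are noise.
separable_table <- function(n = 80, seed = 7, flip = 0) {
  set.seed(seed)
  label <- rep(c("repressed", "nonrepressed"), each = n / 2)
  f1 <- ifelse(label == "repressed", 1, 0) + rnorm(n, 0, 0.05)
  if (flip > 0) {
    idx <- sample(n, flip)
    f1[idx] <- 1 - round(f1[idx])
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             f1 = f1, f2 = rnorm(n), f3 = rnorm(n), f4 = runif(n),
             label = label, stringsAsFactors = FALSE)
}
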
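## ---------------------------------------------------------------------------
## Co-occurrence statistics between region sets and gene sets
##
## The overlap unit is "share at least 1 bp" under the half-open coordinate
## convention. Significance is a signed natural-log hypergeometric tail:
## values <= 0 mark enrichment (observed >= expected), values >= 0 mark
## depletion/divergence. All tails are computed in log space via phyper.
## ---------------------------------------------------------------------------

#' Count regions of A overlapping any region of B
#'
#' Each A region is counted once no matter how many B regions it touches;
#' "overlap" means sharing at least 1 bp.
#'
#' @param set_a,set_b interval data.frames (chrom/start/end).
#' @return integer count.
#' @export
count_overlaps <- function(set_a, set_b) {
  if (!nrow(set_a) || !nrow(set_b)) return(0L)
  sum(GenomicRanges::countOverlaps(intervals_to_granges(set_a),
                                   intervals_to_granges(set_b)) > 0)
}

#' Signed natural-log hypergeometric tail
#'
#' For \code{k} observed overlaps between a set of size \code{K} and a set
#' of size \code{n} drawn from a universe of size \code{N}: when \code{k}
#' meets or exceeds the expectation \code{K*n/N} the value is
#' \code{ln P(X >= k)} (non-positive, enrichment); otherwise it is
#' \code{-ln P(X <= k)} (non-negative, divergence). Computed in log space,
#' stable for universes up to at least 1e6.
#'
#' @param k observed overlap count.
#' @param K,n the two set sizes.
#' @param N universe size.
#' @return signed natural-log p-value.
#' @export
hypergeom_signed_ln_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("invalid hypergeometric counts: need k <= min(K, n) <= N")
  expected <- K * n / N
  if (k >= expected) {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  } else {
    -phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  }
}

#' Hypergeometric overlap between two gene sets
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @param universe_genes character vector containing both sets.
#' @return list of class \code{overlap_result}: \code{n_a}, \code{n_b},
#'   \code{n_overlap}, \code{universe_n}, \code{signed_ln_p}.
#' @export
gene_set_overlap <- function(genes_a, genes_b, universe_genes) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  universe_genes <- unique(universe_genes)
  if (!all(genes_a %in% universe_genes) || !all(genes_b %in% universe_genes))
    stop("gene sets must be subsets of the universe")
  k <- length(intersect(genes_a, genes_b))
  res <- list(n_a = length(genes_a), n_b = length(genes_b), n_overlap = k,
              universe_n = length(universe_genes),
              signed_ln_p = hypergeom_signed_ln_p(k, length(genes_a),
                                                  length(genes_b),
                                                  length(universe_genes)))
  structure(res, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: %d/%d vs %d overlap in universe %d; signed ln p = %.3f (%s)\n",
    x$n_overlap, x$n_a, x$n_b, x$universe_n, x$signed_ln_p,
    if (x$signed_ln_p <= 0) "enrichment" else "divergence"))
  invisible(x)
}

## Universe model for region-level tests: the genome as a row of placement
## slots, one per mean region width of the pooled sets.
region_universe_n <- function(set_a, set_b, genome_length) {
  widths <- c(interval_width(set_a), interval_width(set_b))
  if (!length(widths)) return(max(1, round(genome_length)))
  max(1, round(genome_length / mean(widths)))
}

#' Hypergeometric overlap between two region sets
#'
#' The universe size is modeled as genome length divided by the mean width
#' of the pooled region sets (a places-on-genome model), a stated convention
#' documented with the result.
#'
#' @param set_a,set_b interval data.frames.
#' @param genome_length total genome length (bp).
#' @return an \code{overlap_result}.
#' @export
region_set_overlap <- function(set_a, set_b, genome_length) {
  k <- count_overlaps(set_a, set_b)
  K <- nrow(set_a); n <- nrow(set_b)
  N <- max(region_universe_n(set_a, set_b, genome_length), K, n)
  k <- min(k, n)   # guard: one wide A region can touch many B regions
  res <- list(n_a = K, n_b = n, n_overlap = k, universe_n = N,
              signed_ln_p = hypergeom_signed_ln_p(k, K, n, N))
  structure(res, class = "overlap_result")
}

#' Pairwise co-occurrence matrix over region categories
#'
#' Computes the signed natural-log hypergeometric overlap significance for
#' every pair of region categories (typically mark x direction). Each
#' off-diagonal cell is computed once (first category as the counted set)
#' and mirrored, so the matrix is symmetric by construction; the diagonal is
#' each category's self-enrichment. Empty categories yield zero rows.
#'
#' @param region_sets named list of interval data.frames.
#' @param genome_length total genome length (bp).
#' @return numeric matrix of signed ln p-values with category dimnames.
#' @export
cooccurrence_matrix <- function(region_sets, genome_length) {
  if (length(region_sets) < 2) stop("need at least two region categories")
  nm <- names(region_sets)
  m <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      a <- region_sets[[i]]; b <- region_sets[[j]]
      if (!nrow(a) || !nrow(b)) next
      v <- region_set_overlap(a, b, genome_length)$signed_ln_p
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}
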
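## ---------------------------------------------------------------------------
## Composite profiles, heatmap matrices, scatter comparisons and block-width
## distribution tests around affected regions.
##
## Profiles are centered on region midpoints (marks are strandless, so no
## strand flipping for region-centered views). Track values are converted to
## per-bp densities (count / track bin size), replicates averaged.
## ---------------------------------------------------------------------------

## Per-bp density matrix around region midpoints: rows = regions, cols = bp.
perbp_matrix <- function(track, regions, window) {
  half <- window %/% 2
  mids <- region_midpoint(regions)
  bin <- track$bin_size
  n_rep <- length(track$counts)
  m <- matrix(0, nrow(regions), window)
  offsets <- seq_len(window) - 1 - half
  pooled <- lapply(names(track$chrom_lengths), function(chr)
    Reduce(`+`, lapply(track$counts, function(rc) rc[[chr]])) / n_rep)
  names(pooled) <- names(track$chrom_lengths)
  for (i in seq_len(nrow(regions))) {
    v <- pooled[[regions$chrom[i]]]
    pos <- mids[i] + offsets
    idx <- pos %/% bin + 1
    ok <- pos >= 0 & idx <= length(v)
    m[i, ok] <- v[idx[ok]] / bin
  }
  m
}

#' Composite signal profile around regions
#'
#' Mean signal density in a window centered on region midpoints, in
#' per-bp-per-region units, averaged over replicates.
#'
#' @param track a normalized \code{signal_track}.
#' @param regions interval data.frame (must be non-empty).
#' @param window total window width (bp), centered.
#' @param bin profile bin size (bp); \code{window / bin} bins result.
#' @return list of class \code{composite_profile}: \code{values} (per-bin
#'   mean density), \code{bin_size}, \code{window}, \code{n_regions}.
#' @export
composite_profile <- function(track, regions, window = 4000, bin = 10) {
  if (!nrow(regions)) stop("region list is empty")
  if (window %% bin != 0) stop("window must be a multiple of bin")
  m <- perbp_matrix(track, regions, window)
  perbp <- colMeans(m)
  values <- colMeans(matrix(perbp, nrow = bin))
  structure(list(values = values, bin_size = bin, window = window,
                 n_regions = nrow(regions)), class = "composite_profile")
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("composite_profile: %d bins of %d bp over %d regions (mean %.4g/bp)\n",
              length(x$values), x$bin_size, x$n_regions, mean(x$values)))
  invisible(x)
}

#' @export
#' @method plot composite_profile
plot.composite_profile <- function(x, ...) {
  off <- (seq_along(x$values) - 0.5) * x$bin_size - x$window / 2
  plot(off, x$values, type = "l", xlab = "distance from region center (bp)",
       ylab = "signal per bp per region", ...)
  invisible(x)
}

#' Per-region heatmap matrix around regions
#'
#' Total tags per bin in a window centered on region midpoints (one row per
#' region), optionally ranked by a key such as peak height.
#'
#' @param track a normalized \code{signal_track}.
#' @param regions interval data.frame.
#' @param window total window width (bp).
#' @param bin matrix bin size (bp).
#' @param rank_by optional numeric vector (one per region); rows are sorted
#'   by it in decreasing order.
#' @return list of class \code{heatmap_matrix}: \code{matrix} (regions x
#'   bins of tag counts), \code{bin_size}, \code{window}, \code{order}.
#' @export
heatmap_matrix <- function(track, regions, window = 5000, bin = 25,
                           rank_by = NULL) {
  if (!nrow(regions)) stop("region list is empty")
  if (window %% bin != 0) stop("window must be a multiple of bin")
  m <- perbp_matrix(track, regions, window)
  nbin <- window / bin
  tags <- sapply(seq_len(nbin), function(j)
    rowSums(m[, ((j - 1) * bin + 1):(j * bin), drop = FALSE]))
  tags <- matrix(tags, nrow = nrow(regions))
  ord <- seq_len(nrow(regions))
  if (!is.null(rank_by)) {
    if (length(rank_by) != nrow(regions))
      stop("rank_by must have one value per region")
    ord <- order(rank_by, decreasing = TRUE)
    tags <- tags[ord, , drop = FALSE]
  }
  structure(list(matrix = tags, bin_size = bin, window = window, order = ord),
            class = "heatmap_matrix")
}

#' Scatter comparison of two tracks over a peak set
#'
#' Total tags per peak in each track, log2-transformed with pseudocount 1,
#' plus their Pearson correlation.
#'
#' @param track_a,track_b normalized \code{signal_track}s.
#' @param peaks interval data.frame with at least 2 rows.
#' @return list: \code{log2_a}, \code{log2_b}, \code{pearson_r}.
#' @export
scatter_compare <- function(track_a, track_b, peaks) {
  if (nrow(peaks) < 2) stop("need at least two peaks for a correlation")
  tags <- function(track) {
    bin <- track$bin_size
    n_rep <- length(track$counts)
    pooled <- lapply(names(track$chrom_lengths), function(chr)
      Reduce(`+`, lapply(track$counts, function(rc) rc[[chr]])) / n_rep)
    names(pooled) <- names(track$chrom_lengths)
    vapply(seq_len(nrow(peaks)), function(i) {
      v <- pooled[[peaks$chrom[i]]]
      pos <- peaks$start[i]:(peaks$end[i] - 1)
      idx <- pos %/% bin + 1
      ok <- idx >= 1 & idx <= length(v)
      sum(v[idx[ok]] / bin)
    }, numeric(1))
  }
  a <- log2(tags(track_a) + 1)
  b <- log2(tags(track_b) + 1)
  list(log2_a = a, log2_b = b, pearson_r = cor(a, b))
}

#' Compare two block-width distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the width distributions (e.g.
#' repressor-bound vs unbound blocks), plus the sample means.
#'
#' @param widths_bound,widths_unbound numeric width samples (>= 2 each).
#' @return list: \code{ks_statistic}, \code{p_value}, \code{mean_bound},
#'   \code{mean_unbound}.
#' @export
compare_block_widths <- function(widths_bound, widths_unbound) {
  if (length(widths_bound) < 2 || length(widths_unbound) < 2)
    stop("need at least two widths per sample")
  ks <- suppressWarnings(ks.test(widths_bound, widths_unbound))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       mean_bound = mean(widths_bound), mean_unbound = mean(widths_unbound))
}
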
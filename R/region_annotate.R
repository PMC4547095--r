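## ---------------------------------------------------------------------------
## Region-to-gene annotation
##
## Nearest-TSS assignment (region midpoint, tie broken by lower gene_id),
## genomic-context classification with promoter > exon > intron > intergenic
## precedence, repressor-bound linkage, and promoter/gene-body Pol II change
## classification.
## ---------------------------------------------------------------------------

region_midpoint <- function(regions) floor((regions$start + regions$end) / 2)

#' Assign regions to the gene with the nearest TSS
#'
#' Distance is measured from the region midpoint to each TSS; the gene
#' minimizing the absolute distance wins, ties broken by the
#' lexicographically smaller \code{gene_id}. The reported distance is
#' strand-oriented: positive downstream of the TSS, negative upstream.
#' Regions on chromosomes without genes get \code{NA} assignments.
#'
#' @param regions interval data.frame (chrom/start/end).
#' @param genes a \code{\link{gene_set}}.
#' @return data.frame with one row per region: \code{gene_id},
#'   \code{tss_distance}.
#' @export
nearest_tss <- function(regions, genes) {
  g <- genes$genes
  if (!nrow(g)) stop("gene set is empty")
  mid <- region_midpoint(regions)
  gene_id <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  for (chr in unique(regions$chrom)) {
    gc <- g[g$chrom == chr, , drop = FALSE]
    ri <- which(regions$chrom == chr)
    if (!nrow(gc)) next
    gc <- gc[order(gc$gene_id), , drop = FALSE]
    d <- abs(outer(mid[ri], gc$tss, "-"))
    best <- apply(d, 1, which.min)   # first minimum = smallest gene_id on tie
    gene_id[ri] <- gc$gene_id[best]
    signed <- mid[ri] - gc$tss[best]
    dist[ri] <- ifelse(gc$strand[best] == "+", signed, -signed)
  }
  data.frame(gene_id = gene_id, tss_distance = dist, stringsAsFactors = FALSE)
}

## Strand-oriented half-open interval [tss + lo, tss + hi) in offset space.
oriented_window <- function(tss, strand, lo, hi) {
  start <- ifelse(strand == "+", tss + lo, tss - hi + 1)
  end <- ifelse(strand == "+", tss + hi, tss - lo + 1)
  data.frame(start = start, end = end)
}

#' Classify the genomic context of regions
#'
#' A region's midpoint is tested against all genes with precedence
#' promoter > exon > intron > intergenic. The promoter window is
#' strand-oriented, default 1 kb upstream to 100 bp downstream of the TSS.
#'
#' @param regions interval data.frame.
#' @param genes a \code{\link{gene_set}}.
#' @param promoter_window numeric length-2 strand-oriented offsets
#'   \code{c(upstream, downstream)} defining \code{[TSS+up, TSS+down)}.
#' @return character vector of contexts.
#' @export
classify_context <- function(regions, genes, promoter_window = c(-1000, 100)) {
  g <- genes$genes
  mid <- region_midpoint(regions)
  pw <- oriented_window(g$tss, g$strand, promoter_window[1],
                        promoter_window[2])
  point_in <- function(starts, ends, chroms, pts, pts_chrom) {
    if (!length(starts)) return(rep(FALSE, length(pts)))
    gr_pt <- GenomicRanges::GRanges(pts_chrom, IRanges::IRanges(pts + 1,
                                                                pts + 1))
    gr_iv <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts + 1, ends))
    GenomicRanges::countOverlaps(gr_pt, gr_iv) > 0
  }
  in_prom <- point_in(pw$start, pw$end, g$chrom, mid, regions$chrom)
  in_exon <- point_in(genes$exons$start, genes$exons$end, genes$exons$chrom,
                      mid, regions$chrom)
  in_gene <- point_in(g$start, g$end, g$chrom, mid, regions$chrom)
  ifelse(in_prom, "promoter",
         ifelse(in_exon, "exon", ifelse(in_gene, "intron", "intergenic")))
}

#' Annotate regions with nearest gene, TSS distance and genomic context
#'
#' @inheritParams classify_context
#' @return The input regions with \code{gene_id}, \code{tss_distance} and
#'   \code{context} columns appended.
#' @export
annotate_regions <- function(regions, genes, promoter_window = c(-1000, 100)) {
  nt <- nearest_tss(regions, genes)
  cbind(regions, nt,
        data.frame(context = classify_context(regions, genes, promoter_window),
                   stringsAsFactors = FALSE))
}

#' Flag blocks whose nearest gene is bound by the repressor
#'
#' Peaks are first assigned to their nearest-TSS gene; a block is flagged
#' bound iff its own nearest gene carries at least one assigned peak.
#'
#' @param blocks interval data.frame of differential blocks.
#' @param peaks peak data.frame (chrom/start/end).
#' @param genes a \code{\link{gene_set}}.
#' @return logical vector, one per block.
#' @export
link_hairy_bound <- function(blocks, peaks, genes) {
  if (!nrow(blocks)) return(logical(0))
  peak_genes <- if (nrow(peaks)) unique(nearest_tss(peaks, genes)$gene_id)
                else character(0)
  block_genes <- nearest_tss(blocks, genes)$gene_id
  !is.na(block_genes) & block_genes %in% peak_genes
}

#' Classify per-gene Pol II occupancy change
#'
#' Categorizes each gene by whether Pol II decrease-blocks overlap its
#' promoter (strand-oriented window around the TSS), its gene body (from
#' \code{body_offset} bp downstream of the TSS to the gene end, separating
#' paused-promoter from elongation signal), both, or neither.
#'
#' @param genes a \code{\link{gene_set}}.
#' @param polII_blocks data.frame of Pol II decrease-blocks.
#' @param promoter_window strand-oriented promoter offsets (see
#'   \code{\link{classify_context}}).
#' @param body_offset bp downstream of the TSS where the gene body starts.
#' @return data.frame with \code{gene_id} and \code{polII_change} in
#'   \{\code{promoter_only}, \code{body_only}, \code{both}, \code{none}\}.
#' @export
classify_polII_change <- function(genes, polII_blocks,
                                  promoter_window = c(-1000, 100),
                                  body_offset = 250) {
  g <- genes$genes
  pw <- oriented_window(g$tss, g$strand, promoter_window[1],
                        promoter_window[2])
  body_start <- ifelse(g$strand == "+", g$tss + body_offset, g$start)
  body_end <- ifelse(g$strand == "+", g$end, g$tss - body_offset + 1)
  overlaps_any <- function(starts, ends) {
    valid <- ends > starts
    hit <- rep(FALSE, length(starts))
    if (!nrow(polII_blocks) || !any(valid)) return(hit)
    gr_g <- GenomicRanges::GRanges(g$chrom[valid],
                                   IRanges::IRanges(starts[valid] + 1,
                                                    ends[valid]))
    gr_b <- intervals_to_granges(polII_blocks)
    hit[valid] <- GenomicRanges::countOverlaps(gr_g, gr_b) > 0
    hit
  }
  in_prom <- overlaps_any(pw$start, pw$end)
  in_body <- overlaps_any(body_start, body_end)
  cls <- ifelse(in_prom & in_body, "both",
                ifelse(in_prom, "promoter_only",
                       ifelse(in_body, "body_only", "none")))
  data.frame(gene_id = g$gene_id, polII_change = cls, stringsAsFactors = FALSE)
}
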
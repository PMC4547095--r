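#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats rnbinom rlnorm runif rnorm rexp rgamma pnorm phyper
#'   var weighted.mean cor ks.test quantile setNames predict sd ave rpois
#'   dist
#' @importFrom graphics plot
#' @importFrom utils read.table write.table head
NULL

## ---------------------------------------------------------------------------
## Genomic intervals
##
## All coordinates in this package are 0-based, half-open [start, end), the
## native BED/bedGraph convention. GFF3 input is shifted on read. Intervals
## live in plain data frames (chrom/start/end) so they serialize trivially;
## conversion to GRanges is used wherever IRanges machinery does the work.
## ---------------------------------------------------------------------------

#' Construct a validated set of genomic intervals
#'
#' Intervals are 0-based, half-open \code{[start, end)}. Width is
#' \code{end - start}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; \code{start >= 0}, \code{end > start}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}.
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (length(chrom) == 1) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start))
    stop("chrom must have length 1 or length(start)")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be greater than start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval widths
#' @param x interval data.frame (chrom/start/end).
#' @return numeric vector of widths (bp).
#' @export
interval_width <- function(x) x$end - x$start

#' Convert half-open intervals to GRanges (1-based closed) and back
#' @param x interval data.frame.
#' @return a \code{GRanges} object.
#' @export
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' @rdname intervals_to_granges
#' @param gr a \code{GRanges}.
#' @export
granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## SignalTrack
## ---------------------------------------------------------------------------

#' Construct a binned signal track
#'
#' A signal track stores per-chromosome vectors of non-negative binned read
#' counts for one chromatin mark in one condition, with one vector set per
#' replicate. Bin \code{i} covers \code{[(i-1)*bin_size, i*bin_size)}.
#'
#' @param mark mark identifier (e.g. \code{"H4Ac"}, \code{"PolII"}).
#' @param condition \code{"wt"} or \code{"induced"}.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param counts list of replicates; each replicate a named list of numeric
#'   vectors, one per chromosome, of length \code{ceiling(length / bin_size)}.
#' @return An object of class \code{signal_track}.
#' @export
signal_track <- function(mark, condition, bin_size, chrom_lengths, counts) {
  condition <- match.arg(condition, c("wt", "induced"))
  if (!length(counts)) stop("at least one replicate required")
  for (r in seq_along(counts)) {
    rep_counts <- counts[[r]]
    if (!setequal(names(rep_counts), names(chrom_lengths)))
      stop("replicate ", r, ": chromosome names do not match chrom_lengths")
    for (chr in names(chrom_lengths)) {
      v <- rep_counts[[chr]]
      nbin <- ceiling(chrom_lengths[[chr]] / bin_size)
      if (length(v) != nbin)
        stop("replicate ", r, " chromosome ", chr, ": expected ", nbin,
             " bins, got ", length(v))
      if (any(v < 0)) stop("negative counts in replicate ", r, " (", chr, ")")
    }
  }
  structure(list(mark = mark, condition = condition, bin_size = bin_size,
                 chrom_lengths = chrom_lengths, counts = counts),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %s [%s], %d replicate(s), bin %d bp, %d chrom(s)\n",
              x$mark, x$condition, length(x$counts), x$bin_size,
              length(x$chrom_lengths)))
  cat(sprintf("  total tags per replicate: %s\n",
              paste(format(total_tags(x), big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Total tags per replicate
#' @param track a \code{signal_track}.
#' @return numeric vector, one total per replicate.
#' @export
total_tags <- function(track) {
  vapply(track$counts, function(rep_counts) sum(unlist(rep_counts,
                                                       use.names = FALSE)),
         numeric(1))
}

#' Library-size normalization
#'
#' Scales every replicate so that its total tag count equals
#' \code{target_total} (default ten million), the conventional
#' reads-per-ten-million normalization for ChIP-seq coverage tracks.
#' Idempotent at the target and ratio-preserving between bins.
#'
#' @param track a \code{signal_track}.
#' @param target_total target sum per replicate.
#' @return A normalized \code{signal_track}.
#' @export
normalize_track <- function(track, target_total = 1e7) {
  totals <- total_tags(track)
  if (any(totals <= 0)) stop("cannot normalize a replicate with zero total tags")
  track$counts <- lapply(seq_along(track$counts), function(r) {
    f <- target_total / totals[r]
    lapply(track$counts[[r]], function(v) v * f)
  })
  track
}

## ---------------------------------------------------------------------------
## bedGraph IO
##
## bedGraph is read with a strict 4-column parser so malformed lines are
## reported with their line number and a varying bin size is rejected --
## guarantees the downstream window arithmetic relies on.
## ---------------------------------------------------------------------------

read_bedgraph_one <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty bedGraph: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    stop("malformed bedGraph line ", bad[1], " in ", path,
         ": expected 4 tab-separated fields")
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop("malformed bedGraph line ", bad[1], " in ", path,
         ": non-numeric coordinate or value")
  if (any(value < 0)) {
    bad <- which(value < 0)[1]
    stop("negative value at bedGraph line ", bad, " in ", path)
  }
  widths <- end - start
  if (any(widths <= 0))
    stop("malformed bedGraph line ", which(widths <= 0)[1], " in ", path,
         ": end must exceed start")
  bin <- widths[1]
  if (any(widths != bin))
    stop("inconsistent bin size in ", path, ": expected ", bin,
         " bp, line ", which(widths != bin)[1], " has ", widths[widths != bin][1])
  if (any(start %% bin != 0))
    stop("bins not aligned to a ", bin, " bp grid in ", path)
  list(chrom = m[, 1], start = start, end = end, value = value, bin = bin)
}

#' Read replicate bedGraph files into a signal track
#'
#' @param paths character vector of bedGraph paths, one per replicate.
#' @param mark,condition track metadata.
#' @param chrom_lengths optional named chromosome lengths; inferred from the
#'   rightmost covered bin when omitted. Uncovered bins are zero-filled.
#' @return A \code{signal_track}.
#' @export
read_tracks <- function(paths, mark = "mark", condition = "wt",
                        chrom_lengths = NULL) {
  parsed <- lapply(paths, read_bedgraph_one)
  bins <- vapply(parsed, function(p) p$bin, numeric(1))
  if (length(unique(bins)) != 1)
    stop("replicates disagree on bin size: ", paste(bins, collapse = ", "))
  bin <- bins[1]
  if (is.null(chrom_lengths)) {
    ends <- do.call(rbind, lapply(parsed, function(p)
      data.frame(chrom = p$chrom, end = p$end)))
    chrom_lengths <- tapply(ends$end, ends$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  counts <- lapply(parsed, function(p) {
    out <- lapply(names(chrom_lengths), function(chr) {
      nbin <- ceiling(chrom_lengths[[chr]] / bin)
      v <- numeric(nbin)
      sel <- p$chrom == chr
      idx <- p$start[sel] / bin + 1
      if (any(idx > nbin)) stop("bin beyond chromosome end on ", chr)
      v[idx] <- p$value[sel]
      v
    })
    names(out) <- names(chrom_lengths)
    out
  })
  signal_track(mark, condition, bin, chrom_lengths, counts)
}

#' Write a signal track as one bedGraph per replicate
#'
#' @param track a \code{signal_track}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are
#'   \code{<prefix>_rep<i>.bedGraph}.
#' @return Invisibly, the written paths.
#' @export
write_tracks <- function(track, dir,
                         prefix = paste0(track$mark, "_", track$condition)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(track$counts))
  for (r in seq_along(track$counts)) {
    rows <- lapply(names(track$chrom_lengths), function(chr) {
      v <- track$counts[[r]][[chr]]
      n <- length(v)
      data.frame(chrom = chr,
                 start = (seq_len(n) - 1) * track$bin_size,
                 end = seq_len(n) * track$bin_size,
                 value = v, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    paths[r] <- file.path(dir, sprintf("%s_rep%d.bedGraph", prefix, r))
    write.table(format(df, scientific = FALSE, trim = TRUE), paths[r],
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(paths)
}

## ---------------------------------------------------------------------------
## Gene models
## ---------------------------------------------------------------------------

#' Construct a gene set
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (\code{+}/\code{-}). The TSS is
#'   derived from the strand: \code{start} on \code{+}, \code{end - 1} on
#'   \code{-} (half-open convention; the last covered base).
#' @param exons data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}; exons must lie within their gene and be disjoint.
#' @return An object of class \code{gene_set}: a list with elements
#'   \code{genes} (with a derived \code{tss} column) and \code{exons}.
#' @export
gene_set <- function(genes, exons = NULL) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand value; must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  idx <- match(exons$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("exon refers to unknown gene")
  if (any(exons$start < genes$start[idx] | exons$end > genes$end[idx]))
    stop("exon outside its gene span")
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in gene ", g)
  }
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 rows of type \code{gene} become genes; \code{exon} rows are attached
#' through their \code{Parent} attribute. BED12 blocks become exons.
#' Coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path input file.
#' @param format \code{"gff3"} or \code{"bed12"}.
#' @return A \code{gene_set}.
#' @export
read_genes <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    types <- as.character(gr$type)
    g <- gr[types == "gene"]
    if (!length(g)) stop("no gene records in ", path)
    strand <- as.character(GenomicRanges::strand(g))
    if (any(!strand %in% c("+", "-"))) stop("unknown strand in ", path)
    genes <- data.frame(gene_id = as.character(g$ID),
                        chrom = as.character(GenomicRanges::seqnames(g)),
                        start = GenomicRanges::start(g) - 1,
                        end = GenomicRanges::end(g),
                        strand = strand, stringsAsFactors = FALSE)
    e <- gr[types == "exon"]
    exons <- if (length(e)) {
      parent <- vapply(e$Parent, function(p) as.character(p)[1], character(1))
      data.frame(gene_id = parent,
                 chrom = as.character(GenomicRanges::seqnames(e)),
                 start = GenomicRanges::start(e) - 1,
                 end = GenomicRanges::end(e), stringsAsFactors = FALSE)
    } else NULL
  } else {
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-"))) stop("unknown strand in ", path)
    genes <- data.frame(gene_id = as.character(gr$name),
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1,
                        end = GenomicRanges::end(gr),
                        strand = strand, stringsAsFactors = FALSE)
    exons <- NULL
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      rows <- lapply(seq_along(gr), function(i) {
        b <- bl[[i]]
        data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                   start = genes$start[i] + (GenomicRanges::start(b) - 1),
                   end = genes$start[i] + GenomicRanges::end(b),
                   stringsAsFactors = FALSE)
      })
      exons <- do.call(rbind, rows)
    }
  }
  gene_set(genes, exons)
}

#' Write gene models as GFF3
#' @param genes a \code{gene_set}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_genes <- function(genes, path) {
  g <- genes$genes
  ggr <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(g$start + 1, g$end),
                                strand = g$strand)
  ggr$type <- "gene"
  ggr$ID <- g$gene_id
  e <- genes$exons
  if (nrow(e)) {
    idx <- match(e$gene_id, g$gene_id)
    egr <- GenomicRanges::GRanges(e$chrom,
                                  IRanges::IRanges(e$start + 1, e$end),
                                  strand = g$strand[idx])
    egr$type <- "exon"
    egr$ID <- paste0(e$gene_id, ":exon", stats::ave(seq_len(nrow(e)),
                                                    e$gene_id, FUN = seq_along))
    egr$Parent <- as.character(e$gene_id)
    all <- c(ggr, egr)
  } else all <- ggr
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Peaks and expression tables
## ---------------------------------------------------------------------------

#' Read a factor peak set from BED
#'
#' The BED score column is taken as the peak height.
#'
#' @param path BED file.
#' @param factor_id factor label (e.g. \code{"Hairy"}).
#' @return data.frame with \code{factor_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{height}, sorted by chrom/start.
#' @export
read_peaks <- function(path, factor_id) {
  gr <- rtracklayer::import(path, format = "bed")
  height <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(1, length(gr))
  if (any(height <= 0)) stop("peak height must be positive")
  df <- data.frame(factor_id = factor_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   height = height, stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write a peak set as BED
#' @param peaks peak data.frame (see \code{\link{read_peaks}}).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_peaks <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  gr$name <- paste0(peaks$factor_id, "_", seq_len(nrow(peaks)))
  gr$score <- peaks$height
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write a gene expression table
#'
#' Tab-separated with header columns \code{gene_id}, \code{wt_level},
#' \code{fold_change} (induced/wt), \code{p_value}.
#'
#' @param path TSV path.
#' @return data.frame of expression records.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "wt_level", "fold_change", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("expression table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_expression
#' @param expression expression data.frame.
#' @export
write_expression <- function(expression, path) {
  write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
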
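## ---------------------------------------------------------------------------
## Per-gene 41-feature table
##
## Four aggregate features per differential dataset (block count, total block
## width, max |log2FC|, min |TSS distance|), four per binding factor (peak
## count, total width, max height, min |TSS distance|), plus wild-type
## expression. Genes without linked regions get zero counts/widths/FCs and
## the distance cap as a finite, rankable sentinel.
## ---------------------------------------------------------------------------

#' Label genes by the differential-expression filter
#'
#' A gene is repressed when \code{fold_change <= 1/fc_min} with
#' \code{p_value < p_max}, activated when \code{fold_change >= fc_min} with
#' \code{p_value < p_max}, otherwise unaffected. For classification,
#' activated and unaffected genes pool into \code{nonrepressed}.
#'
#' @param expression data.frame with \code{gene_id}, \code{fold_change}
#'   (induced/wt, > 0) and \code{p_value}.
#' @param p_max,fc_min filter thresholds.
#' @return data.frame: \code{gene_id}, \code{class} (repressed / activated /
#'   unaffected), \code{label} (repressed / nonrepressed).
#' @export
select_regulated_genes <- function(expression, p_max = 0.05, fc_min = 2) {
  if (anyNA(expression$fold_change) || anyNA(expression$p_value))
    stop("expression table has missing fold_change or p_value")
  if (any(expression$fold_change <= 0)) stop("fold_change must be positive")
  fc <- expression$fold_change
  sig <- expression$p_value < p_max
  cls <- ifelse(sig & fc <= 1 / fc_min, "repressed",
                ifelse(sig & fc >= fc_min, "activated", "unaffected"))
  data.frame(gene_id = expression$gene_id, class = cls,
             label = ifelse(cls == "repressed", "repressed", "nonrepressed"),
             stringsAsFactors = FALSE)
}

aggregate_regions <- function(regions, genes, magnitude, distance_cap) {
  ann <- nearest_tss(regions, genes)
  df <- data.frame(gene_id = ann$gene_id,
                   width = interval_width(regions),
                   magnitude = magnitude,
                   dist = pmin(abs(ann$tss_distance), distance_cap))
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  sp <- split(df, df$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    count = vapply(sp, nrow, numeric(1)),
    width_total = vapply(sp, function(x) sum(x$width), numeric(1)),
    magnitude_max = vapply(sp, function(x) max(x$magnitude), numeric(1)),
    dist_min = vapply(sp, function(x) min(x$dist), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the per-gene 41-feature table
#'
#' Blocks and peaks are assigned to genes by nearest TSS, then aggregated
#' per gene and dataset. With the full configuration (7 differential
#' datasets, 3 binding factors, wild-type expression) this yields exactly
#' 4*7 + 4*3 + 1 = 41 numeric feature columns plus \code{gene_id} and
#' \code{label}.
#'
#' @param blocks_by_mark named list of differential block data.frames, one
#'   per mark.
#' @param peaks_by_factor named list of peak data.frames (with
#'   \code{height}), one per binding factor.
#' @param expression expression table (see
#'   \code{\link{select_regulated_genes}}); every gene must be present.
#' @param genes a \code{\link{gene_set}}.
#' @param distance_cap distance sentinel (bp) for genes without a linked
#'   region in a dataset.
#' @param p_max,fc_min differential-expression thresholds for labeling.
#' @return data.frame: \code{gene_id}, 41 feature columns in a stable
#'   documented order (per mark: \code{<mark>_block_count},
#'   \code{<mark>_block_width_total}, \code{<mark>_block_abs_log2fc_max},
#'   \code{<mark>_block_tss_distance_min}; per factor:
#'   \code{<factor>_peak_count}, \code{<factor>_peak_width_total},
#'   \code{<factor>_peak_height_max}, \code{<factor>_peak_tss_distance_min};
#'   then \code{wt_expression}), and \code{label} last.
#' @export
build_feature_table <- function(blocks_by_mark, peaks_by_factor, expression,
                                genes, distance_cap = 1e5, p_max = 0.05,
                                fc_min = 2) {
  gid <- genes$genes$gene_id
  miss <- setdiff(gid, expression$gene_id)
  if (length(miss))
    stop("gene(s) missing from expression table: ",
         paste(head(miss, 3), collapse = ", "))
  tab <- data.frame(gene_id = gid, stringsAsFactors = FALSE)
  add_dataset <- function(tab, regions, magnitude, prefix, kind) {
    cols <- paste0(prefix, "_", kind, "_",
                   c("count", "width_total",
                     if (kind == "block") "abs_log2fc_max" else "height_max",
                     "tss_distance_min"))
    if (is.null(regions) || !nrow(regions)) {
      tab[[cols[1]]] <- 0; tab[[cols[2]]] <- 0; tab[[cols[3]]] <- 0
      tab[[cols[4]]] <- distance_cap
      return(tab)
    }
    agg <- aggregate_regions(regions, genes, magnitude, distance_cap)
    idx <- match(tab$gene_id, agg$gene_id)
    tab[[cols[1]]] <- ifelse(is.na(idx), 0, agg$count[idx])
    tab[[cols[2]]] <- ifelse(is.na(idx), 0, agg$width_total[idx])
    tab[[cols[3]]] <- ifelse(is.na(idx), 0, agg$magnitude_max[idx])
    tab[[cols[4]]] <- ifelse(is.na(idx), distance_cap, agg$dist_min[idx])
    tab
  }
  for (mark in names(blocks_by_mark)) {
    b <- blocks_by_mark[[mark]]
    tab <- add_dataset(tab, b, if (!is.null(b) && nrow(b)) abs(b$log2fc)
                       else numeric(0), mark, "block")
  }
  for (f in names(peaks_by_factor)) {
    p <- peaks_by_factor[[f]]
    tab <- add_dataset(tab, p, if (!is.null(p) && nrow(p)) p$height
                       else numeric(0), f, "peak")
  }
  eidx <- match(tab$gene_id, expression$gene_id)
  tab$wt_expression <- expression$wt_level[eidx]
  lab <- select_regulated_genes(expression[eidx, , drop = FALSE],
                                p_max = p_max, fc_min = fc_min)
  tab$label <- lab$label
  tab
}

#' Feature column names of a feature table
#' @param table a feature table.
#' @return character vector (everything but \code{gene_id} and \code{label}).
#' @export
feature_columns <- function(table) setdiff(names(table), c("gene_id", "label"))

#' Write / read a feature table as TSV
#' @param table feature table.
#' @param path TSV path.
#' @return Invisibly \code{path} / the table.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
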
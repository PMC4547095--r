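## ---------------------------------------------------------------------------
## Differential chromatin block detection
##
## Sliding-window scan of replicated, library-size-normalized coverage,
## negative-binomial Wald test per window, then merging of significant
## same-direction windows into blocks with sub-window boundary refinement.
## ---------------------------------------------------------------------------

#' Detector configuration
#'
#' @param window sliding window width (bp).
#' @param step window step (bp); must divide \code{window} evenly into the
#'   track's bin grid and be \code{<= window}.
#' @param p_max p-value threshold for significant windows.
#' @param lfc_min minimum |log2 fold change| for significant windows.
#' @param pseudocount added to window means before the fold-change log.
#' @param input_filter_factor optional; windows whose mean coverage in both
#'   conditions is below \code{input mean * factor} are dropped.
#' @param refine_bp smoothing width (bp) for block boundary refinement;
#'   \code{NULL} disables refinement.
#' @return list of class \code{detector_config}.
#' @export
detector_config <- function(window = 1000, step = 500, p_max = 0.05,
                            lfc_min = 0.4, pseudocount = 1,
                            input_filter_factor = NULL, refine_bp = 250) {
  if (step > window) stop("step must be <= window")
  if (p_max <= 0 || lfc_min <= 0 || pseudocount <= 0)
    stop("thresholds must be positive")
  structure(list(window = window, step = step, p_max = p_max,
                 lfc_min = lfc_min, pseudocount = pseudocount,
                 input_filter_factor = input_filter_factor,
                 refine_bp = refine_bp),
            class = "detector_config")
}

## Sliding-window sums per replicate for one chromosome: rows = windows.
window_sums <- function(rep_vectors, chrom, n_win, wbins, sbins) {
  sapply(rep_vectors, function(rep_counts) {
    v <- rep_counts[[chrom]]
    cs <- c(0, cumsum(v))
    starts <- (seq_len(n_win) - 1) * sbins
    cs[starts + wbins + 1] - cs[starts + 1]
  })
}

#' Scan the genome for differential windows
#'
#' Slides a window along both tracks, computes replicate-mean window counts
#' per condition, and tests equality of means with a two-sided Wald test on
#' log means using negative-binomial variance. A single common dispersion is
#' estimated by the method of moments across all windows and replicates
#' within each condition; the Wald variance is evaluated at the pooled
#' (null) mean, which makes the test exactly symmetric under condition swap.
#' With fewer than two replicates in both conditions the dispersion cannot
#' be estimated and the test falls back to Poisson (zero dispersion) with a
#' warning.
#'
#' @param track_wt,track_induced normalized \code{signal_track}s with equal
#'   bin size and chromosomes.
#' @param config a \code{\link{detector_config}}.
#' @param input_track optional input/background \code{signal_track} used as
#'   an exclusion filter (see \code{input_filter_factor}).
#' @return data.frame with one row per window: \code{chrom}, \code{start},
#'   \code{end}, \code{mean_wt}, \code{mean_induced}, \code{log2fc},
#'   \code{p_value}.
#' @export
scan_windows <- function(track_wt, track_induced, config = detector_config(),
                         input_track = NULL) {
  if (track_wt$bin_size != track_induced$bin_size)
    stop("tracks disagree on bin size")
  bin <- track_wt$bin_size
  if (config$window %% bin != 0 || config$step %% bin != 0)
    stop("window and step must be multiples of the track bin size")
  wbins <- config$window / bin
  sbins <- config$step / bin
  n1 <- length(track_wt$counts); n2 <- length(track_induced$counts)

  per_chrom <- lapply(names(track_wt$chrom_lengths), function(chr) {
    L <- track_wt$chrom_lengths[[chr]]
    nbin <- floor(L / bin)
    n_win <- max(0, floor((nbin - wbins) / sbins) + 1)
    if (n_win == 0) return(NULL)
    s1 <- matrix(window_sums(track_wt$counts, chr, n_win, wbins, sbins),
                 nrow = n_win)
    s2 <- matrix(window_sums(track_induced$counts, chr, n_win, wbins, sbins),
                 nrow = n_win)
    inp <- if (!is.null(input_track))
      rowMeans(matrix(window_sums(input_track$counts, chr, n_win, wbins,
                                  sbins), nrow = n_win))
    list(chrom = chr, start = (seq_len(n_win) - 1) * config$step,
         s1 = s1, s2 = s2, input = inp)
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  if (!length(per_chrom)) stop("no windows fit on any chromosome")

  s1 <- do.call(rbind, lapply(per_chrom, `[[`, "s1"))
  s2 <- do.call(rbind, lapply(per_chrom, `[[`, "s2"))
  m1 <- rowMeans(s1); m2 <- rowMeans(s2)

  ## common dispersion (NB size^-1) by method of moments, pooled over windows
  phi <- 0
  if (n1 >= 2 || n2 >= 2) {
    num <- 0; den <- 0
    if (n1 >= 2) {
      v1 <- (rowSums(s1^2) - n1 * m1^2) / (n1 - 1)
      num <- num + sum(v1 - m1); den <- den + sum(m1^2)
    }
    if (n2 >= 2) {
      v2 <- (rowSums(s2^2) - n2 * m2^2) / (n2 - 1)
      num <- num + sum(v2 - m2); den <- den + sum(m2^2)
    }
    phi <- max(0, num / den)
  } else {
    warning("fewer than two replicates in both conditions; ",
            "falling back to a Poisson window test")
  }

  c0 <- config$pseudocount
  mp <- (m1 + m2) / 2
  se2 <- (1 / (mp + c0) + phi) * (1 / n1 + 1 / n2)
  z <- (log(m2 + c0) - log(m1 + c0)) / sqrt(se2)
  p <- pmin(1, 2 * pnorm(-abs(z)))

  out <- data.frame(
    chrom = unlist(lapply(per_chrom, function(pc)
      rep(pc$chrom, length(pc$start)))),
    start = unlist(lapply(per_chrom, `[[`, "start")),
    stringsAsFactors = FALSE)
  out$end <- out$start + config$window
  out$mean_wt <- m1
  out$mean_induced <- m2
  out$log2fc <- log2((m2 + c0) / (m1 + c0))
  out$p_value <- p

  if (!is.null(config$input_filter_factor) && !is.null(input_track)) {
    inp <- unlist(lapply(per_chrom, `[[`, "input"))
    keep <- m1 >= inp * config$input_filter_factor |
      m2 >= inp * config$input_filter_factor
    out <- out[keep, , drop = FALSE]
  }
  out
}

## Refine one merged block to the outermost bins whose smoothed log2fc
## passes lfc_min in the block's direction.
refine_block <- function(chrom, start, end, direction, track_wt,
                         track_induced, config) {
  bin <- track_wt$bin_size
  k <- max(1, round(config$refine_bp / bin))
  i0 <- start / bin + 1
  i1 <- end / bin
  pool <- function(track) {
    m <- rowMeans(sapply(track$counts, function(rc) rc[[chrom]][i0:i1]))
    as.numeric(stats::filter(m, rep(1 / k, k), sides = 2, circular = FALSE))
  }
  sw <- pool(track_wt); si <- pool(track_induced)
  slfc <- log2((si + config$pseudocount / k) / (sw + config$pseudocount / k))
  ok <- if (direction == "decrease") slfc < -config$lfc_min
        else slfc > config$lfc_min
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(c(start, end))
  idx <- range(which(ok))
  c(start + (idx[1] - 1) * bin, start + idx[2] * bin)
}

#' Merge significant windows into differential blocks
#'
#' Keeps windows with \code{p < p_max} and \code{|log2fc| > lfc_min}, merges
#' touching or overlapping windows of the same direction, and summarizes each
#' block: width-weighted mean log2 fold change, minimum member p-value and
#' member window count. When the two tracks are supplied, block boundaries
#' are refined to the outermost bins whose smoothed (default 250 bp)
#' log2 fold change still passes \code{lfc_min} in the block's direction;
#' this removes the half-window overshoot that merging step-overlapping
#' windows otherwise adds at block edges.
#'
#' @param windows output of \code{\link{scan_windows}}.
#' @param config a \code{\link{detector_config}}.
#' @param track_wt,track_induced optional tracks enabling boundary
#'   refinement.
#' @return data.frame of blocks: \code{chrom}, \code{start}, \code{end},
#'   \code{direction}, \code{log2fc}, \code{p_value}, \code{n_windows}.
#' @export
merge_and_filter <- function(windows, config = detector_config(),
                             track_wt = NULL, track_induced = NULL) {
  sig <- windows[windows$p_value < config$p_max &
                   abs(windows$log2fc) > config$lfc_min, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), log2fc = numeric(),
                      p_value = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig$direction <- ifelse(sig$log2fc < 0, "decrease", "increase")
  out <- list()
  for (dir in c("decrease", "increase")) {
    sd_win <- sig[sig$direction == dir, , drop = FALSE]
    if (!nrow(sd_win)) next
    gr <- intervals_to_granges(sd_win)
    merged <- GenomicRanges::reduce(gr, min.gapwidth = 1)
    hits <- GenomicRanges::findOverlaps(merged, gr)
    for (b in seq_along(merged)) {
      members <- sd_win[subjectHits(hits)[queryHits(hits) == b], , drop = FALSE]
      bchrom <- as.character(GenomicRanges::seqnames(merged))[b]
      bstart <- GenomicRanges::start(merged)[b] - 1
      bend <- GenomicRanges::end(merged)[b]
      if (!is.null(track_wt) && !is.null(track_induced) &&
          !is.null(config$refine_bp)) {
        se <- refine_block(bchrom, bstart, bend, dir, track_wt,
                           track_induced, config)
        bstart <- se[1]; bend <- se[2]
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = bchrom, start = bstart, end = bend, direction = dir,
        log2fc = weighted.mean(members$log2fc,
                               members$end - members$start),
        p_value = min(members$p_value),
        n_windows = nrow(members), stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, out)
  blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
}

#' Call differential blocks for one mark
#'
#' Convenience wrapper: \code{\link{scan_windows}} followed by
#' \code{\link{merge_and_filter}} with boundary refinement.
#'
#' @inheritParams scan_windows
#' @return data.frame of blocks (see \code{\link{merge_and_filter}}).
#' @export
call_blocks <- function(track_wt, track_induced, config = detector_config(),
                        input_track = NULL) {
  w <- scan_windows(track_wt, track_induced, config, input_track)
  merge_and_filter(w, config, track_wt, track_induced)
}

#' Call differential blocks for every mark of a cohort
#'
#' Tracks are library-size normalized to ten million tags before scanning.
#' Marks missing either condition are skipped with a warning.
#'
#' @param cohort a \code{synthetic_cohort} (or any list with a \code{tracks}
#'   element of per-mark \code{wt}/\code{induced} tracks).
#' @param config a \code{\link{detector_config}}.
#' @return Named list: per mark, a data.frame of blocks with a \code{mark}
#'   column added.
#' @export
call_blocks_all_marks <- function(cohort, config = detector_config()) {
  out <- list()
  for (mark in names(cohort$tracks)) {
    pair <- cohort$tracks[[mark]]
    if (is.null(pair$wt) || is.null(pair$induced)) {
      warning("mark ", mark, " lacks a condition; skipped")
      next
    }
    wt <- normalize_track(pair$wt)
    ind <- normalize_track(pair$induced)
    blocks <- call_blocks(wt, ind, config)
    if (nrow(blocks)) blocks$mark <- mark
    else blocks$mark <- character(0)
    out[[mark]] <- blocks
  }
  out
}

#' Write blocks as BED6+ (score = -10 log10 p, extra columns log2fc,
#' direction, n_windows)
#' @param blocks block data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_blocks <- function(blocks, path) {
  if (!nrow(blocks)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = blocks$chrom, start = blocks$start,
                   end = blocks$end,
                   name = if ("mark" %in% names(blocks) && nrow(blocks))
                     blocks$mark else rep(".", nrow(blocks)),
                   score = round(-10 * log10(pmax(blocks$p_value, 1e-300)), 2),
                   strand = ".", log2fc = blocks$log2fc,
                   direction = blocks$direction, n_windows = blocks$n_windows,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
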
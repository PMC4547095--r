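## ---------------------------------------------------------------------------
## Synthetic embryo cohort generator
##
## Emulates the statistical structure the downstream analysis assumes:
## replicate NB-distributed window counts for six histone marks + Pol II (+ an
## H3 density control) in wild-type and repressor-induced conditions, planted
## differential blocks whose presence correlates with gene class,
## repressor/cofactor peak sets enriched near repressed genes, and a
## 241/146/196 repressed/activated/unaffected expression cohort. Every draw is
## seeded; sub-seeds are derived from the cohort seed by fixed offsets so the
## stages are individually reproducible.
## ---------------------------------------------------------------------------

DIFF_MARKS <- c("H4Ac", "H3K27Ac", "H3K4me1", "H3K4me3", "H3K36me3",
                "H3K9me3", "PolII")
BINDING_FACTORS <- c("Hairy", "CtBP", "Gro")

#' Configuration for a synthetic cohort
#'
#' Defaults encode the study conditions: 583 genes split 241 repressed /
#' 146 activated / 196 unaffected, six histone marks plus Pol II (and an H3
#' density control that carries no planted effects), 25-bp bins, three
#' replicates per condition, negative-binomial background counts, planted
#' blocks with |log2 fold change| 1.5 and gamma-distributed widths
#' (H4Ac mean 2.5 kb), and repressor/cofactor peaks enriched near repressed
#' genes. A fraction of nonrepressed genes also receives planted blocks
#' ("errant targeting"), which keeps chromatin state and expression partly
#' uncoupled and the classification task nontrivial.
#'
#' @param seed integer RNG seed for the cohort.
#' @param n_chroms,chrom_length genome shape (bp per chromosome).
#' @param n_genes total genes; \code{class_counts} must sum to it.
#' @param class_counts named counts for repressed/activated/unaffected.
#' @param marks differential marks to simulate (H3 control added via
#'   \code{control_marks}).
#' @param control_marks marks simulated with no planted effects.
#' @param bin_size bp per bin.
#' @param nb_mean,nb_dispersion negative-binomial background mean and size
#'   per bin.
#' @param n_replicates replicates per condition.
#' @param block_width_mean named mean planted block width (bp) per mark.
#' @param block_width_shape gamma shape for planted widths.
#' @param planted_effect_log2fc magnitude of the planted log2 fold change.
#' @param p_block_given_repressed probability a repressed gene carries
#'   planted blocks.
#' @param p_block_given_nonrepressed probability a nonrepressed gene carries
#'   planted blocks (errant targeting).
#' @param p_mark_given_carrier named probability each mark is planted on a
#'   carrier gene.
#' @param background_block_rate per-gene, per-mark rate of unrelated blocks
#'   with random direction.
#' @param peak_enrichment probability a repressed gene receives a peak for
#'   each binding factor.
#' @param background_peak_rate peak probability for nonrepressed genes.
#' @param expr_lfc_shift,expr_lfc_rate regulated genes draw
#'   |log2 fold change| = shift + Exp(rate).
#' @return A validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(seed = 1,
                          n_chroms = 4,
                          chrom_length = 1.2e6,
                          n_genes = 583,
                          class_counts = c(repressed = 241, activated = 146,
                                           unaffected = 196),
                          marks = DIFF_MARKS,
                          control_marks = "H3",
                          bin_size = 25,
                          nb_mean = 5,
                          nb_dispersion = 10,
                          n_replicates = 3,
                          block_width_mean = c(H4Ac = 2500, H3K27Ac = 2000,
                                               H3K4me1 = 2000, H3K4me3 = 1500,
                                               H3K36me3 = 2000, H3K9me3 = 1500,
                                               PolII = 2000),
                          block_width_shape = 4,
                          planted_effect_log2fc = 1.5,
                          p_block_given_repressed = 0.8,
                          p_block_given_nonrepressed = 0.3,
                          p_mark_given_carrier = c(H4Ac = 0.9, H3K27Ac = 0.7,
                                                   H3K4me1 = 0.7, H3K4me3 = 0.5,
                                                   H3K36me3 = 0.5, H3K9me3 = 0.3,
                                                   PolII = 0.6),
                          background_block_rate = 0.05,
                          peak_enrichment = 0.8,
                          background_peak_rate = 0.15,
                          expr_lfc_shift = 1.5,
                          expr_lfc_rate = 1) {
  cfg <- as.list(environment())
  probs <- c(p_block_given_repressed, p_block_given_nonrepressed,
             peak_enrichment, background_peak_rate, background_block_rate,
             p_mark_given_carrier)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (sum(class_counts) != n_genes)
    stop("class_counts must sum to n_genes")
  if (!all(marks %in% names(block_width_mean)))
    stop("block_width_mean must name every differential mark")
  if (any(block_width_mean <= 0)) stop("block widths must be positive")
  if (nb_mean <= 0 || nb_dispersion <= 0) stop("NB parameters must be positive")
  structure(cfg, class = "cohort_config")
}

## increase for the repressive mark, decrease for everything else
planted_direction <- function(mark) {
  ifelse(mark == "H3K9me3", "increase", "decrease")
}

sub_seed <- function(seed, offset) (seed + offset) %% .Machine$integer.max

#' Generate a synthetic genome of non-overlapping gene territories
#'
#' Genes are spread evenly across chromosomes; each gene occupies a random
#' sub-interval of its private territory with a random strand and 2-4 exons.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{chrom_lengths} (named numeric) and \code{genes}
#'   (a \code{\link{gene_set}} whose genes carry a \code{territory_start} /
#'   \code{territory_end} pair).
#' @export
generate_genome <- function(config) {
  set.seed(sub_seed(config$seed, 0))
  n <- config$n_genes
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
  per_chrom <- diff(floor(n * (0:config$n_chroms) / config$n_chroms))
  territory <- floor(config$chrom_length / max(per_chrom))
  if (territory < 5000)
    stop("genome too small for ", n, " gene territories (",
         territory, " bp each)")
  rows <- list()
  gi <- 0
  for (ci in seq_len(config$n_chroms)) {
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1
      t0 <- (k - 1) * territory
      glen <- round(runif(1, 1000, min(4000, territory - 1000)))
      gstart <- t0 + round(runif(1, 200, territory - glen - 200))
      rows[[gi]] <- data.frame(
        gene_id = sprintf("g%04d", gi), chrom = chroms[ci],
        start = gstart, end = gstart + glen,
        strand = sample(c("+", "-"), 1),
        territory_start = t0, territory_end = t0 + territory,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  exon_rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_ex <- sample(2:4, 1)
    len <- g$end - g$start
    cuts <- sort(sample(seq(50, len - 50, by = 25), 2 * n_ex - 1))
    bounds <- c(0, cuts, len)
    keep <- seq(1, 2 * n_ex, by = 2)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = g$start + bounds[keep],
               end = g$start + bounds[keep + 1], stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exon_rows)
  list(chrom_lengths = chrom_lengths, genes = gene_set(genes, exons))
}

## Draw the planted differential blocks for one cohort.
plant_blocks <- function(config, genome, classes) {
  set.seed(sub_seed(config$seed, 1e6))
  genes <- genome$genes$genes
  carrier_p <- ifelse(classes == "repressed",
                      config$p_block_given_repressed,
                      config$p_block_given_nonrepressed)
  carrier <- runif(nrow(genes)) < carrier_p
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (mark in config$marks) {
      planted <- carrier[i] && runif(1) < config$p_mark_given_carrier[[mark]]
      background <- runif(1) < config$background_block_rate
      if (!planted && !background) next
      w <- rgamma(1, shape = config$block_width_shape,
                  scale = config$block_width_mean[[mark]] /
                    config$block_width_shape)
      w <- max(200, round(w / config$bin_size) * config$bin_size)
      center <- round(g$tss + rnorm(1, 0, 1000))
      t0 <- ceiling(g$territory_start / config$bin_size) * config$bin_size
      t1 <- floor(g$territory_end / config$bin_size) * config$bin_size
      start <- max(t0, round((center - w / 2) / config$bin_size) *
                     config$bin_size)
      end <- min(t1, start + w)
      if (end - start < 200) next
      dir <- if (planted) planted_direction(mark)
             else sample(c("decrease", "increase"), 1)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g$gene_id, mark = mark, chrom = g$chrom,
        start = start, end = end, direction = dir,
        log2fc = ifelse(dir == "decrease", -1, 1) * config$planted_effect_log2fc,
        planted = planted, stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), mark = character(), chrom = character(),
               start = numeric(), end = numeric(), direction = character(),
               log2fc = numeric(), planted = logical())
  list(blocks = blocks, carrier = carrier)
}

simulate_tracks <- function(config, genome, blocks) {
  set.seed(sub_seed(config$seed, 2e6))
  chroms <- names(genome$chrom_lengths)
  nbins <- ceiling(genome$chrom_lengths / config$bin_size)
  all_marks <- c(config$marks, config$control_marks)
  tracks <- list()
  for (mark in all_marks) {
    mu_wt <- lapply(chroms, function(chr) rep(config$nb_mean, nbins[[chr]]))
    names(mu_wt) <- chroms
    mu_ind <- mu_wt
    mb <- blocks[blocks$mark == mark, , drop = FALSE]
    for (j in seq_len(nrow(mb))) {
      b <- mb[j, ]
      idx <- (b$start / config$bin_size + 1):(b$end / config$bin_size)
      idx <- idx[idx >= 1 & idx <= nbins[[b$chrom]]]
      mu_ind[[b$chrom]][idx] <- mu_ind[[b$chrom]][idx] * 2^b$log2fc
    }
    draw <- function(mu_list) {
      lapply(seq_len(config$n_replicates), function(r) {
        out <- lapply(mu_list, function(mu)
          as.numeric(rnbinom(length(mu), mu = mu, size = config$nb_dispersion)))
        names(out) <- chroms
        out
      })
    }
    tracks[[mark]] <- list(
      wt = signal_track(mark, "wt", config$bin_size, genome$chrom_lengths,
                        draw(mu_wt)),
      induced = signal_track(mark, "induced", config$bin_size,
                             genome$chrom_lengths, draw(mu_ind)))
  }
  tracks
}

plant_peaks <- function(config, genome, classes) {
  set.seed(sub_seed(config$seed, 3e6))
  genes <- genome$genes$genes
  rows <- list()
  for (f in BINDING_FACTORS) {
    p <- ifelse(classes == "repressed", config$peak_enrichment,
                config$background_peak_rate)
    has <- runif(nrow(genes)) < p
    for (i in which(has)) {
      g <- genes[i, ]
      n_pk <- 1 + stats::rpois(1, 0.4)
      for (k in seq_len(n_pk)) {
        w <- round(runif(1, 300, 800))
        center <- if (classes[i] == "repressed")
          round(g$tss + rnorm(1, 0, 500))
        else round(runif(1, g$territory_start + w, g$territory_end - w))
        center <- min(max(center, g$territory_start + w %/% 2),
                      g$territory_end - w %/% 2)
        start <- max(g$territory_start, center - w %/% 2)
        end <- min(g$territory_end, start + w)
        rows[[length(rows) + 1]] <- data.frame(
          factor_id = f, chrom = g$chrom, start = start, end = end,
          height = rlnorm(1, log(50), 0.5), gene_id = g$gene_id,
          enriched = classes[i] == "repressed", stringsAsFactors = FALSE)
      }
    }
  }
  peaks <- do.call(rbind, rows)
  peaks[order(peaks$factor_id, peaks$chrom, peaks$start), , drop = FALSE]
}

simulate_expression <- function(config, genes, classes) {
  set.seed(sub_seed(config$seed, 4e6))
  n <- length(classes)
  lfc <- numeric(n); p <- numeric(n); wt <- numeric(n)
  reg <- classes != "unaffected"
  mag <- config$expr_lfc_shift + rexp(n, config$expr_lfc_rate)
  lfc[classes == "repressed"] <- -mag[classes == "repressed"]
  lfc[classes == "activated"] <- mag[classes == "activated"]
  lfc[!reg] <- rnorm(sum(!reg), 0, 0.2)
  p[reg] <- runif(sum(reg), 1e-8, 0.01)
  p[!reg] <- runif(sum(!reg), 0.1, 1)
  wt[reg] <- rlnorm(sum(reg), 4, 1)
  wt[!reg] <- rlnorm(sum(!reg), 3.5, 1)
  data.frame(gene_id = genes$gene_id, wt_level = wt, fold_change = 2^lfc,
             p_value = p, stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Runs genome layout, block planting, NB track simulation, peak planting and
#' expression simulation under the config's seed and returns everything along
#' with the planted ground truth.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return An object of class \code{synthetic_cohort}: a list with
#'   \code{config}, \code{chrom_lengths}, \code{genes} (a \code{gene_set}),
#'   \code{tracks} (per mark, \code{wt}/\code{induced} signal tracks),
#'   \code{peaks} (per binding factor), \code{expression}, and \code{truth}
#'   (\code{gene_classes}, \code{blocks}, \code{peaks}).
#' @export
generate_cohort <- function(config = cohort_config()) {
  genome <- generate_genome(config)
  set.seed(sub_seed(config$seed, 5e5))
  classes <- sample(rep(names(config$class_counts), config$class_counts))
  planted <- plant_blocks(config, genome, classes)
  tracks <- simulate_tracks(config, genome, planted$blocks)
  peaks <- plant_peaks(config, genome, classes)
  expression <- simulate_expression(config, genome$genes$genes, classes)
  truth <- list(
    gene_classes = data.frame(gene_id = genome$genes$genes$gene_id,
                              class = classes,
                              carries_blocks = planted$carrier,
                              stringsAsFactors = FALSE),
    blocks = planted$blocks,
    peaks = peaks)
  peak_sets <- lapply(BINDING_FACTORS, function(f)
    peaks[peaks$factor_id == f,
          c("factor_id", "chrom", "start", "end", "height"), drop = FALSE])
  names(peak_sets) <- BINDING_FACTORS
  structure(list(config = config, chrom_lengths = genome$chrom_lengths,
                 genes = genome$genes, tracks = tracks, peaks = peak_sets,
                 expression = expression, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes on %d chromosome(s), %d track mark(s)\n",
              nrow(x$genes$genes), length(x$chrom_lengths), length(x$tracks)))
  print(table(x$truth$gene_classes$class))
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' bedGraph per mark/condition/replicate, BED per binding factor, GFF3 gene
#' models, TSV expression table and a JSON ground-truth file.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mark in names(cohort$tracks))
    for (cond in c("wt", "induced"))
      write_tracks(cohort$tracks[[mark]][[cond]], dir)
  for (f in names(cohort$peaks))
    write_peaks(cohort$peaks[[f]], file.path(dir, paste0(f, "_peaks.bed")))
  write_genes(cohort$genes, file.path(dir, "genes.gff3"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(list(chrom_lengths = as.list(cohort$chrom_lengths),
                            marks = names(cohort$tracks),
                            n_replicates = cohort$config$n_replicates,
                            bin_size = cohort$config$bin_size),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a written cohort dataset back from disk
#'
#' @param dir directory produced by \code{\link{write_dataset}}.
#' @return A list with \code{tracks}, \code{peaks}, \code{genes},
#'   \code{expression}, \code{truth}, \code{chrom_lengths}.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  chrom_lengths <- unlist(meta$chrom_lengths)
  tracks <- list()
  for (mark in meta$marks) {
    tracks[[mark]] <- list()
    for (cond in c("wt", "induced")) {
      paths <- file.path(dir, sprintf("%s_%s_rep%d.bedGraph", mark, cond,
                                      seq_len(meta$n_replicates)))
      tracks[[mark]][[cond]] <- read_tracks(paths, mark, cond, chrom_lengths)
    }
  }
  peak_files <- list.files(dir, pattern = "_peaks\\.bed$", full.names = TRUE)
  peaks <- lapply(peak_files, function(p)
    read_peaks(p, sub("_peaks\\.bed$", "", basename(p))))
  names(peaks) <- sub("_peaks\\.bed$", "", basename(peak_files))
  list(tracks = tracks, peaks = peaks,
       genes = read_genes(file.path(dir, "genes.gff3"), "gff3"),
       expression = read_expression(file.path(dir, "expression.tsv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE),
       chrom_lengths = chrom_lengths)
}
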
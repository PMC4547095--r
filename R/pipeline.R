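## ---------------------------------------------------------------------------
## End-to-end pipeline driver: simulate -> write -> normalize -> diffblocks
## -> annotate -> co-occurrence -> profiles -> features -> classify.
## Stages communicate through files in standard formats so each is
## independently re-readable; a manifest records parameters, seeds and file
## digests.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param detector a \code{\link{detector_config}}.
#' @param ml an \code{\link{ml_config}}.
#' @param out_dir output directory.
#' @param promoter_window strand-oriented promoter offsets.
#' @param distance_cap feature-table distance sentinel (bp).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            detector = detector_config(),
                            ml = ml_config(),
                            out_dir = tempfile("chromcode_run_"),
                            promoter_window = c(-1000, 100),
                            distance_cap = 1e5) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(detector, "detector_config"),
            inherits(ml, "ml_config"))
  structure(list(cohort = cohort, detector = detector, ml = ml,
                 out_dir = out_dir, promoter_window = promoter_window,
                 distance_cap = distance_cap), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, writes the dataset, calls differential blocks for
#' every mark, annotates blocks to genes, computes the mark x direction
#' co-occurrence matrix, a composite H4Ac profile around decrease blocks,
#' the bound/unbound block-width comparison, the 41-feature table and the
#' full selection x classification grid. All stage outputs land in
#' \code{out_dir}; a manifest with parameters, seeds and md5 digests of the
#' written files makes reruns checkable.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the key in-memory objects
#'   (\code{cohort}, \code{blocks}, \code{features}, \code{fit}) and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- stage("simulate", generate_cohort(config$cohort))
  stage("write_dataset", write_dataset(cohort, file.path(config$out_dir,
                                                         "dataset")))
  blocks <- stage("diffblocks", call_blocks_all_marks(cohort, config$detector))
  for (mark in names(blocks))
    write_blocks(blocks[[mark]],
                 file.path(config$out_dir, paste0("blocks_", mark, ".bed")))

  all_blocks <- do.call(rbind, blocks[vapply(blocks, nrow, numeric(1)) > 0])
  annotated <- stage("annotate", {
    if (!is.null(all_blocks) && nrow(all_blocks)) {
      ann <- annotate_regions(all_blocks, cohort$genes,
                              config$promoter_window)
      ann$hairy_bound <- link_hairy_bound(all_blocks, cohort$peaks$Hairy,
                                          cohort$genes)
      ann
    } else NULL
  })
  if (!is.null(annotated))
    write.table(annotated, file.path(config$out_dir, "blocks_annotated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  genome_length <- sum(cohort$chrom_lengths)
  stage("cooccurrence", {
    sets <- list()
    for (mark in names(blocks))
      for (dir in c("decrease", "increase")) {
        sel <- blocks[[mark]][blocks[[mark]]$direction == dir, , drop = FALSE]
        sets[[paste(mark, dir, sep = ".")]] <- sel
      }
    keep <- vapply(sets, nrow, numeric(1)) > 0
    if (sum(keep) >= 2) {
      m <- cooccurrence_matrix(sets[keep], genome_length)
      write.table(m, file.path(config$out_dir, "cooccurrence.tsv"),
                  sep = "\t", quote = FALSE)
    }
  })

  stage("profiles", {
    h4 <- blocks[["H4Ac"]]
    if (!is.null(h4)) {
      dec <- h4[h4$direction == "decrease", , drop = FALSE]
      if (nrow(dec)) {
        prof <- composite_profile(normalize_track(cohort$tracks$H4Ac$wt), dec)
        write.table(data.frame(bin = seq_along(prof$values),
                               value = prof$values),
                    file.path(config$out_dir, "H4Ac_profile.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(annotated)) {
          h4a <- annotated[annotated$mark == "H4Ac" &
                             annotated$direction == "decrease", , drop = FALSE]
          if (sum(h4a$hairy_bound) >= 2 && sum(!h4a$hairy_bound) >= 2) {
            cmpw <- compare_block_widths(
              interval_width(h4a[h4a$hairy_bound, ]),
              interval_width(h4a[!h4a$hairy_bound, ]))
            jsonlite::write_json(cmpw,
                                 file.path(config$out_dir, "block_widths.json"),
                                 auto_unbox = TRUE, digits = NA)
          }
        }
      }
    }
  })

  ## the H3 density control is scanned but is not a classifier feature
  diff_blocks <- blocks[intersect(config$cohort$marks, names(blocks))]
  features <- stage("features", build_feature_table(
    diff_blocks, cohort$peaks, cohort$expression, cohort$genes,
    distance_cap = config$distance_cap))
  write_feature_table(features, file.path(config$out_dir, "features.tsv"))

  fit <- stage("classify", run_chromatin_code(features, config$ml))
  write.table(fit$evaluation, file.path(config$out_dir, "evaluation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prediction_report(fit),
              file.path(config$out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- sort(list.files(config$out_dir, recursive = TRUE,
                           full.names = TRUE))
  manifest <- list(
    seeds = list(cohort = config$cohort$seed, ml = config$ml$base_seed),
    parameters = list(
      n_genes = config$cohort$n_genes,
      window = config$detector$window, step = config$detector$step,
      p_max = config$detector$p_max, lfc_min = config$detector$lfc_min,
      top_k = config$ml$top_k, n_folds = config$ml$n_folds,
      n_iterations = config$ml$n_iterations),
    digests = as.list(setNames(unname(tools::md5sum(files)),
                               sub(paste0(config$out_dir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, blocks = blocks, features = features,
                 fit = fit, out_dir = config$out_dir,
                 manifest = manifest))
}
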
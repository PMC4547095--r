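test_that("genome generation is deterministic with disjoint territories", {
  cfg <- cohort_config(seed = 11)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genes$genes, g2$genes$genes)
  expect_equal(nrow(g1$genes$genes), 583)

  # territories (and hence genes) are disjoint within each chromosome
  g <- g1$genes$genes
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, ]
    gc <- gc[order(gc$start), ]
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }

  tiny <- cohort_config(seed = 1, n_chroms = 1, chrom_length = 3e4,
                        n_genes = 2,
                        class_counts = c(repressed = 1, activated = 0,
                                         unaffected = 1))
  gt <- generate_genome(tiny)$genes$genes
  expect_equal(nrow(gt), 2)
  expect_true(gt$end[1] <= gt$start[2] || gt$end[2] <= gt$start[1])

  expect_error(generate_genome(cohort_config(n_chroms = 1,
                                             chrom_length = 1e5)),
               "too small")
})

test_that("default cohort has the 241/146/196 class structure and planted truth", {
  cohort <- cached_cohort(1)
  counts <- table(cohort$truth$gene_classes$class)
  expect_equal(as.integer(counts[c("repressed", "activated", "unaffected")]),
               c(241, 146, 196))

  # planted H4Ac widths center on 2.5 kb (gamma mean, modest sampling error)
  bl <- cohort$truth$blocks
  h4 <- bl[bl$mark == "H4Ac" & bl$planted, ]
  expect_gt(nrow(h4), 150)
  expect_lt(abs(mean(h4$end - h4$start) - 2500), 250)

  # every planted block lies inside its own gene's territory
  g <- cohort$genes$genes
  idx <- match(bl$gene_id, g$gene_id)
  expect_true(all(bl$start >= g$territory_start[idx] &
                    bl$end <= g$territory_end[idx]))

  # class-conditional structure points the planted way
  cls <- cohort$truth$gene_classes
  hairy_genes <- cohort$truth$peaks$gene_id[
    cohort$truth$peaks$factor_id == "Hairy"]
  p_rep <- mean(cls$gene_id[cls$class == "repressed"] %in% hairy_genes)
  p_non <- mean(cls$gene_id[cls$class != "repressed"] %in% hairy_genes)
  expect_gt(p_rep, p_non + 0.3)

  # expression labels are consistent with the DE filter by construction
  lab <- select_regulated_genes(cohort$expression)
  expect_equal(lab$class[match(cls$gene_id, lab$gene_id)], cls$class)
})

test_that("same seed gives byte-identical written datasets", {
  cfg <- cohort_config(seed = 5, n_chroms = 1, chrom_length = 1e5,
                       n_genes = 12,
                       class_counts = c(repressed = 5, activated = 3,
                                        unaffected = 4))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(generate_cohort(cfg), d1)
  write_dataset(generate_cohort(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)

  # file count: marks x conditions x replicates bedGraphs
  n_bg <- length(list.files(d1, pattern = "\\.bedGraph$"))
  expect_equal(n_bg, (length(cfg$marks) + length(cfg$control_marks)) * 2 *
                 cfg$n_replicates)

  # round-trip through trackio preserves the cohort
  cohort <- generate_cohort(cfg)
  back <- read_dataset(d1)
  expect_equal(back$tracks$H4Ac$wt$counts, cohort$tracks$H4Ac$wt$counts)
  expect_equal(back$expression, cohort$expression)
  expect_equal(nrow(back$truth$blocks), nrow(cohort$truth$blocks))
  expect_equal(back$genes$genes$tss, cohort$genes$genes$tss)
})

test_that("null config plants nothing and conditions are exchangeable", {
  cfg <- cohort_config(seed = 9, n_chroms = 1, chrom_length = 2e5,
                       n_genes = 20,
                       class_counts = c(repressed = 8, activated = 5,
                                        unaffected = 7),
                       p_block_given_repressed = 0,
                       p_block_given_nonrepressed = 0,
                       background_block_rate = 0)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$truth$blocks), 0)
  blocks <- call_blocks_all_marks(cohort)
  # no planted effects: discovery stays at the chance level
  expect_lte(sum(vapply(blocks, nrow, numeric(1))), 2)
})
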
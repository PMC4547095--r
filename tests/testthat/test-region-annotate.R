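test_that("nearest TSS picks the closest gene with signed distance", {
  gs <- two_gene_set()   # TSS at 1000 (+) and 11999 (-)
  r <- genomic_intervals("chr1", c(2500, 950, 11000), c(3500, 1050, 11200))
  nt <- nearest_tss(r, gs)
  # midpoint 3000: |3000-1000| = 2000 < |3000-11999| -> gA, +2000 downstream
  expect_equal(nt$gene_id, c("gA", "gA", "gB"))
  expect_equal(nt$tss_distance[1], 2000)
  # midpoint exactly on the TSS -> distance 0
  expect_equal(nt$tss_distance[2], 0)
  # gB is - strand: midpoint 11100 is downstream of tss 11999 -> +899
  expect_equal(nt$tss_distance[3], 11999 - 11100)
})

test_that("nearest TSS matches a brute-force scan on random fixtures", {
  set.seed(42)
  for (rep in 1:100) {
    n_g <- sample(2:8, 1)
    genes <- data.frame(
      gene_id = sprintf("g%02d", sample(n_g)),
      chrom = sample(c("chrA", "chrB"), n_g, replace = TRUE),
      start = sample(0:5000, n_g) * 10, strand = sample(c("+", "-"), n_g,
                                                        replace = TRUE),
      stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(500:2000, n_g)
    gs <- gene_set(genes)
    r <- data.frame(chrom = sample(c("chrA", "chrB"), 5, replace = TRUE),
                    start = sample(0:50000, 5))
    r$end <- r$start + sample(100:1000, 5)
    got <- nearest_tss(r, gs)
    for (i in seq_len(5)) {
      cand <- gs$genes[gs$genes$chrom == r$chrom[i], ]
      if (!nrow(cand)) { expect_true(is.na(got$gene_id[i])); next }
      mid <- floor((r$start[i] + r$end[i]) / 2)
      d <- abs(mid - cand$tss)
      best <- cand$gene_id[d == min(d)]
      expect_equal(got$gene_id[i], sort(best)[1])
      expect_equal(abs(got$tss_distance[i]), min(d))
    }
  }
})

test_that("ties go to the lexicographically smaller gene id", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      start = c(2000, 0), end = c(3000, 1000),
                      strand = "+", stringsAsFactors = FALSE)
  gs <- gene_set(genes)   # TSS at 2000 and 0; midpoint 1000 is equidistant
  r <- genomic_intervals("chr1", 990, 1010)
  expect_equal(nearest_tss(r, gs)$gene_id, "gA")
})

test_that("genomic context follows promoter > exon > intron > intergenic", {
  gs <- two_gene_set()
  r <- genomic_intervals(
    "chr1",
    c(940, 3290, 2590, 6990, 9990),
    c(960, 3310, 2610, 7010, 10010))
  ctx <- classify_context(r, gs)
  # midpoint 950: 50 bp upstream of gA's TSS -> promoter
  # midpoint 3300: inside gA exon 2 -> exon
  # midpoint 2600: inside gA span, not exon -> intron
  # midpoint 7000: between territories -> intergenic
  # midpoint 10000: inside gB exon -> exon
  expect_equal(ctx, c("promoter", "exon", "intron", "intergenic", "exon"))
  # contexts partition all regions
  expect_true(all(ctx %in% c("promoter", "exon", "intron", "intergenic")))
})

test_that("repressor-bound linkage uses the nearest gene's peaks", {
  gs <- two_gene_set()
  blocks <- genomic_intervals("chr1", c(2000, 10000), c(2400, 10400))
  peaks <- genomic_intervals("chr1", c(900, 1200), c(1100, 1500))  # both near gA
  bound <- link_hairy_bound(blocks, peaks, gs)
  expect_equal(bound, c(TRUE, FALSE))

  cohort <- cached_cohort(1)
  blocks_all <- cached_blocks(1)
  h4 <- blocks_all$H4Ac
  bound <- link_hairy_bound(h4, cohort$peaks$Hairy, cohort$genes)
  frac_dec <- mean(bound[h4$direction == "decrease"])
  frac_inc <- mean(bound[h4$direction == "increase"])
  expect_gt(frac_dec, frac_inc)
})

test_that("Pol II change classification distinguishes promoter and body", {
  gs <- two_gene_set()   # gA: + strand, tss 1000, body [1250, 4000)
  both <- genomic_intervals("chr1", c(700, 2000), c(1200, 2500))
  prom <- genomic_intervals("chr1", 400, 1050)
  body <- genomic_intervals("chr1", 2000, 2600)
  none <- genomic_intervals("chr1", 6000, 6400)
  get <- function(blocks)
    classify_polII_change(gs, blocks)$polII_change[1]
  expect_equal(get(both), "both")
  expect_equal(get(prom), "promoter_only")
  expect_equal(get(body), "body_only")
  expect_equal(get(none), "none")
  expect_equal(classify_polII_change(gs, none[0, ])$polII_change,
               c("none", "none"))
})
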
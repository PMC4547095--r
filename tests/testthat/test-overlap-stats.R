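test_that("overlap counting honors the 1 bp half-open rule", {
  a <- genomic_intervals("chr1", 100, 200)
  expect_equal(count_overlaps(a, genomic_intervals("chr1", 199, 300)), 1)
  expect_equal(count_overlaps(a, genomic_intervals("chr1", 200, 300)), 0)
  # an A region overlapping two B regions still counts once
  b2 <- genomic_intervals("chr1", c(100, 150), c(140, 190))
  expect_equal(count_overlaps(a, b2), 1)
  expect_equal(count_overlaps(b2, a), 2)
})

test_that("overlap counting equals the quadratic brute force on random sets", {
  set.seed(13)
  for (rep in 1:100) {
    mk <- function(n) {
      s <- sample(0:2000, n)
      data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                 start = s, end = s + sample(10:200, n))
    }
    a <- mk(50); b <- mk(50)
    brute <- sum(vapply(seq_len(nrow(a)), function(i)
      any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i]),
      logical(1)))
    expect_equal(count_overlaps(a, b), brute)
  }
})

test_that("hypergeometric tails equal exhaustive pmf enumeration", {
  set.seed(7)
  for (rep in 1:200) {
    N <- sample(2:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    got <- hypergeom_signed_ln_p(k, K, n, N)
    pmf <- stats::dhyper(0:min(K, n), K, N - K, n)
    expected <- K * n / N
    want <- if (k >= expected) log(sum(pmf[(k + 1):length(pmf)]))
            else -log(sum(pmf[1:(k + 1)]))
    expect_equal(got, want, tolerance = 1e-9)
    # sign convention: enrichment <= 0 iff observed >= expected
    if (k >= expected) expect_lte(got, 0) else expect_gte(got, 0)
  }
  expect_error(hypergeom_signed_ln_p(5, 4, 10, 20), "invalid")
})

test_that("identical sets give growing maximal enrichment; empty sets give 0", {
  v10 <- hypergeom_signed_ln_p(10, 10, 10, 100)
  v20 <- hypergeom_signed_ln_p(20, 20, 20, 100)
  expect_lt(v10, -10)
  expect_lt(v20, v10)
  expect_equal(hypergeom_signed_ln_p(0, 5, 0, 100), 0)
  # no underflow deep in the tail of a large universe
  deep <- hypergeom_signed_ln_p(500, 1000, 1000, 1e6)
  expect_true(is.finite(deep) && deep < -1000)
})

test_that("gene-set overlap matches enumeration and sign conventions", {
  universe <- sprintf("g%03d", 1:100)
  a <- universe[1:5]; b <- universe[1:10]   # a subset of b
  res <- gene_set_overlap(a, b, universe)
  expect_equal(res$n_overlap, 5)
  pmf <- stats::dhyper(0:5, 5, 95, 10)
  expect_equal(res$signed_ln_p, log(pmf[6]), tolerance = 1e-9)
  # disjoint sets with positive expectation -> positive (divergence)
  res2 <- gene_set_overlap(universe[1:20], universe[21:60], universe)
  expect_gt(res2$signed_ln_p, 0)
  expect_error(gene_set_overlap(c("zzz"), b, universe), "universe")
})

test_that("repressed genes are enriched among repressor-bound genes", {
  cohort <- cached_cohort(1)
  cls <- cohort$truth$gene_classes
  hairy_genes <- unique(nearest_tss(cohort$peaks$Hairy,
                                    cohort$genes)$gene_id)
  res <- gene_set_overlap(cls$gene_id[cls$class == "repressed"],
                          hairy_genes, cls$gene_id)
  expect_lt(res$signed_ln_p, -20)
})

test_that("co-occurrence matrix is symmetric with enriched planted pairs", {
  blocks <- cached_blocks(1)
  cohort <- cached_cohort(1)
  G <- sum(cohort$chrom_lengths)
  pick <- function(mark, dir) {
    b <- blocks[[mark]]
    b[b$direction == dir, , drop = FALSE]
  }
  sets <- list(H4Ac.decrease = pick("H4Ac", "decrease"),
               H3K27Ac.decrease = pick("H3K27Ac", "decrease"),
               H3K27Ac.increase = pick("H3K27Ac", "increase"),
               empty = pick("H4Ac", "decrease")[0, ])
  m <- cooccurrence_matrix(sets, G)
  expect_equal(m, t(m))
  # self-enrichment is the row's most negative entry
  expect_equal(which.min(m["H4Ac.decrease", ]), c(H4Ac.decrease = 1L))
  # co-planted decreases are enriched; decrease vs increase is not
  expect_lt(m["H4Ac.decrease", "H3K27Ac.decrease"], -10)
  expect_gt(m["H4Ac.decrease", "H3K27Ac.increase"],
            m["H4Ac.decrease", "H3K27Ac.decrease"])
  expect_true(all(m["empty", ] == 0))
})
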
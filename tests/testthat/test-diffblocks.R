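test_that("identical tracks yield no significant windows", {
  set.seed(21)
  v <- rnbinom(400, mu = 50, size = 10)
  tr <- make_track(v, v, v, condition = "wt")
  ti <- make_track(v, v, v, condition = "induced")
  w <- scan_windows(tr, ti)
  expect_true(all(w$p_value == 1))
  expect_true(all(w$log2fc == 0))
  expect_equal(nrow(merge_and_filter(w)), 0)
})

test_that("window fold change follows the pseudocount formula", {
  # wt mean 100, induced mean 25 per window, c = 1 -> log2(26/101)
  wt <- make_track(rep(2.5, 40), rep(2.5, 40), condition = "wt")
  ind <- make_track(rep(0.625, 40), rep(0.625, 40), condition = "induced")
  w <- scan_windows(wt, ind, detector_config(window = 1000, step = 1000))
  expect_equal(w$mean_wt, 100)
  expect_equal(w$mean_induced, 25)
  expect_equal(w$log2fc, log2(26 / 101), tolerance = 1e-12)
})

test_that("the window test is symmetric under condition swap", {
  set.seed(33)
  a <- nb_track(800, condition = "wt")
  b <- nb_track(800, mu = 6, condition = "induced")
  w_ab <- scan_windows(a, b)
  b$condition <- "wt"; a$condition <- "induced"
  w_ba <- scan_windows(b, a)
  expect_equal(w_ab$log2fc, -w_ba$log2fc, tolerance = 1e-12)
  expect_equal(w_ab$p_value, w_ba$p_value, tolerance = 1e-12)
})

test_that("type-I error of the NB window test is near nominal", {
  # 10,000 independent null windows (step = window so windows don't share
  # bins), NB counts with the generator's per-bin parameters
  set.seed(101)
  nbins <- 10000 * 40
  wt <- nb_track(nbins, condition = "wt")
  ind <- nb_track(nbins, condition = "induced")
  w <- scan_windows(normalize_track(wt), normalize_track(ind),
                    detector_config(window = 1000, step = 1000))
  expect_equal(nrow(w), 10000)
  rate <- mean(w$p_value < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("significant same-direction windows merge into one block", {
  w <- data.frame(chrom = "chr1",
                  start = c(0, 500, 1000, 5000, 8000),
                  end = c(1000, 1500, 2000, 6000, 9000),
                  mean_wt = 100, mean_induced = 25,
                  log2fc = c(-1.5, -1.6, -1.4, 0.3, 1.2),
                  p_value = c(0.001, 0.004, 0.002, 0.01, 0.003))
  b <- merge_and_filter(w, detector_config())
  # three overlapping decrease windows -> one block [0, 2000); the
  # p=0.01/lfc=0.3 window fails the fold-change filter; the last is an
  # increase block of its own
  expect_equal(nrow(b), 2)
  dec <- b[b$direction == "decrease", ]
  expect_equal(c(dec$start, dec$end), c(0, 2000))
  expect_equal(dec$n_windows, 3)
  expect_equal(dec$p_value, 0.001)
  expect_equal(dec$log2fc, weighted.mean(c(-1.5, -1.6, -1.4), c(1000, 1000, 1000)))
  inc <- b[b$direction == "increase", ]
  expect_equal(c(inc$start, inc$end), c(8000, 9000))
})

test_that("a planted 2 kb block is recovered with Jaccard >= 0.8", {
  set.seed(55)
  eff <- list(start = 100000, end = 102000, factor = 2^-1.5)
  wt <- nb_track(8000, condition = "wt")
  ind <- nb_track(8000, condition = "induced", effect = eff)
  blocks <- call_blocks(normalize_track(wt), normalize_track(ind))
  dec <- blocks[blocks$direction == "decrease", ]
  expect_equal(nrow(dec), 1)
  inter <- max(0, min(dec$end, eff$end) - max(dec$start, eff$start))
  union <- max(dec$end, eff$end) - min(dec$start, eff$start)
  expect_gte(inter / union, 0.8)
})

test_that("stronger planted effects never recover fewer blocks", {
  counts <- vapply(c(0.6, 1.0, 1.5), function(lfc) {
    set.seed(77)
    wt <- nb_track(4000, condition = "wt")
    ind <- nb_track(4000, condition = "induced",
                    effect = list(start = 30000, end = 32000,
                                  factor = 2^-lfc))
    set.seed(78)
    nrow(call_blocks(normalize_track(wt), normalize_track(ind)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gte(counts[3], 1)
})

test_that("single-replicate tracks fall back to a Poisson test with warning", {
  set.seed(88)
  wt <- make_track(rnbinom(400, mu = 50, size = 10), condition = "wt")
  ind <- make_track(rnbinom(400, mu = 50, size = 10), condition = "induced")
  expect_warning(w <- scan_windows(wt, ind), "Poisson")
  expect_true(all(w$p_value > 0 & w$p_value <= 1))
})

test_that("per-mark calling flags planted marks and spares the H3 control", {
  cohort <- cached_cohort(1)
  blocks <- cached_blocks(1)
  expect_true(all(names(cohort$tracks) %in%
                    c(names(blocks), character(0))))
  # H3 has no planted effects: at most a stray false call
  expect_lte(nrow(blocks$H3), 2)
  # H4Ac decreases dominate (planted on repressed + errant genes)
  h4 <- blocks$H4Ac
  expect_gt(sum(h4$direction == "decrease"), 100)
  # detected decrease blocks recover most planted ones reciprocally
  truth <- cohort$truth$blocks
  th4 <- truth[truth$mark == "H4Ac" & truth$direction == "decrease", ]
  hit <- count_overlaps(th4, h4[h4$direction == "decrease", ])
  expect_gt(hit / nrow(th4), 0.9)
})
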
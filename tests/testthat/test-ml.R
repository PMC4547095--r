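test_that("information gain and SU equal hand-computed entropies", {
  # 6 rows: x2 splits the label into (3 rep / 1 non) and (0 rep / 2 non)
  tab <- data.frame(gene_id = paste0("g", 1:6),
                    x1 = c(1, 1, 1, 0, 0, 0),
                    x2 = c(1, 1, 1, 1, 0, 0),
                    label = c(rep("repressed", 3), rep("nonrepressed", 3)))
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  hy <- h(c(0.5, 0.5))                      # 1 bit
  # x1 perfectly predicts the label
  ig1 <- rank_features(tab, "info_gain")
  expect_equal(ig1$score[ig1$feature == "x1"], 1)
  expect_equal(ig1$feature[1], "x1")
  # x2: H(Y|X) = 4/6 * h(3/4,1/4) + 2/6 * 0
  ig_x2_hand <- hy - (4 / 6) * h(c(3 / 4, 1 / 4))
  expect_equal(ig1$score[ig1$feature == "x2"], ig_x2_hand, tolerance = 1e-12)
  # SU = 2 IG / (Hx + Hy)
  su <- rank_features(tab, "symmetrical_uncertainty")
  su_x2_hand <- 2 * ig_x2_hand / (h(c(4 / 6, 2 / 6)) + hy)
  expect_equal(su$score[su$feature == "x2"], su_x2_hand, tolerance = 1e-12)
  expect_equal(su$score[su$feature == "x1"], 1)
})

test_that("constant features score zero and constant labels error", {
  tab <- data.frame(gene_id = paste0("g", 1:10),
                    x1 = rep(1, 10), x2 = rnorm(10),
                    label = rep(c("repressed", "nonrepressed"), 5))
  for (m in c("info_gain", "symmetrical_uncertainty", "chi_square")) {
    r <- rank_features(tab, m)
    expect_equal(r$score[r$feature == "x1"], 0, label = m)
  }
  tab$label <- "repressed"
  expect_error(rank_features(tab, "info_gain"), "constant")
})

test_that("chi-square scores match the Pearson statistic", {
  tab <- data.frame(gene_id = paste0("g", 1:8),
                    x1 = c(1, 1, 1, 1, 0, 0, 0, 0),
                    label = c("repressed", "repressed", "repressed",
                              "nonrepressed", "nonrepressed", "nonrepressed",
                              "nonrepressed", "repressed"))
  r <- rank_features(tab, "chi_square")
  want <- suppressWarnings(
    stats::chisq.test(table(tab$x1, tab$label), correct = FALSE))$statistic
  expect_equal(r$score[r$feature == "x1"], unname(want), tolerance = 1e-12)
})

test_that("relief ranks the class-coupled feature first", {
  tab <- separable_table(n = 60, seed = 5)
  r <- rank_features(tab, "relief")
  expect_equal(r$feature[1], "f1")
  expect_gt(r$score[1], 3 * max(abs(r$score[-1])))
})

test_that("every classifier solves a separable table and is deterministic", {
  tab <- separable_table(n = 60, seed = 9)
  for (clf in c("random_forest", "naive_bayes", "knn", "svm")) {
    p1 <- run_iteration(tab, "info_gain", clf, top_k = 2, n_folds = 5,
                        seed = 100)
    expect_equal(unname(p1), tab$label, label = clf)
    p2 <- run_iteration(tab, "info_gain", clf, top_k = 2, n_folds = 5,
                        seed = 100)
    expect_identical(p1, p2, label = clf)
  }
})

test_that("label-permuted data scores near the majority-class baseline", {
  set.seed(31)
  tab <- separable_table(n = 80, seed = 3)
  tab$label <- sample(tab$label)   # destroy the signal, keep 50/50 balance
  votes <- sapply(1:10, function(i)
    run_iteration(tab, "info_gain", "random_forest", top_k = 2, n_folds = 5,
                  seed = 200 + i))
  rec <- aggregate_predictions(votes)
  ev <- evaluate(rec, setNames(tab$label, tab$gene_id))
  expect_lt(abs(ev$overall - 50), 18)   # Monte-Carlo slack around chance
})

test_that("training-fold rankings ignore held-out labels (no leakage)", {
  tab <- separable_table(n = 40, seed = 13)
  set.seed(99)
  folds <- rep(1:4, each = 10)[sample(40)]
  tr <- tab[folds != 1, , drop = FALSE]
  r1 <- rank_features(tr, "info_gain")
  flipped <- tab
  flipped$label[folds == 1] <- rev(flipped$label[folds == 1])
  r2 <- rank_features(flipped[folds != 1, , drop = FALSE], "info_gain")
  expect_identical(r1, r2)
})

test_that("vote aggregation follows the strict majority rule", {
  votes <- rbind(
    g1 = rep("repressed", 50),
    g2 = c(rep("repressed", 26), rep("nonrepressed", 24)),
    g3 = c(rep("repressed", 25), rep("nonrepressed", 25)))
  rec <- aggregate_predictions(votes)
  expect_equal(rec$aggregate_class, c("repressed", "repressed",
                                      "nonrepressed"))
  expect_equal(rec$vote_fraction, c(1, 0.52, 0.5))
  expect_error(aggregate_predictions(rbind(g1 = c("repressed", NA))),
               "missing")
})

test_that("evaluation reports accuracies and the truncated baseline", {
  labels <- setNames(c(rep("repressed", 4), rep("nonrepressed", 6)),
                     paste0("g", 1:10))
  rec <- data.frame(gene_id = paste0("g", 1:10),
                    aggregate_class = c("repressed", "repressed",
                                        "nonrepressed", "repressed",
                                        rep("nonrepressed", 5), "repressed"))
  ev <- evaluate(rec, labels)
  expect_equal(ev$overall, 80)          # 8/10 by hand
  expect_equal(ev$repressed, 75)        # 3/4
  expect_equal(ev$nonrepressed, 100 * 5 / 6)
  expect_equal(ev$baseline_overall, 60)
  expect_equal(ev$baseline_repressed, 40)

  all_right <- data.frame(gene_id = names(labels),
                          aggregate_class = unname(labels))
  expect_equal(evaluate(all_right, labels)$overall, 100)
})

test_that("grid runner reproduces standalone iterations exactly", {
  tab <- separable_table(n = 60, seed = 17, flip = 6)
  cfg <- ml_config(selectors = c("info_gain", "chi_square"),
                   classifiers = c("random_forest", "knn"),
                   top_k = 2, n_folds = 5, n_iterations = 3, base_seed = 42)
  fit <- run_chromatin_code(tab, cfg)
  expect_equal(nrow(fit$evaluation), 4)
  for (iter in 1:3) {
    solo <- run_iteration(tab, "chi_square", "knn", top_k = 2, n_folds = 5,
                          seed = 42 + iter)
    expect_identical(unname(fit$votes[["chi_square.knn"]][, iter]),
                     unname(solo))
  }
  # rerun is bit-identical
  fit2 <- run_chromatin_code(tab, cfg)
  expect_identical(fit$votes, fit2$votes)
})

test_that("prediction report surfaces consistently miscalled genes", {
  tab <- separable_table(n = 40, seed = 23)
  # plant one 'errant' gene: repressed-like features, nonrepressed label
  tab$f1[40] <- 1
  tab$label[40] <- "nonrepressed"
  cfg <- ml_config(selectors = "info_gain",
                   classifiers = c("random_forest", "knn"),
                   top_k = 1, n_folds = 4, n_iterations = 5, base_seed = 7)
  fit <- run_chromatin_code(tab, cfg)
  rep_all <- prediction_report(fit)
  expect_equal(nrow(rep_all), 40)
  errant <- prediction_report(fit, tab$gene_id[40])
  expect_equal(errant$n_correct, 0)
  expect_true(all(errant[, names(fit$records)] == "repressed"))
  empty <- prediction_report(fit, character(0))
  expect_equal(nrow(empty), 0)
})
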
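## ---------------------------------------------------------------------------
## The chromatin code: iterated feature selection / classification /
## majority vote.
##
## Per iteration: stratified 10-fold split; per fold, features are ranked on
## the 90% training part only (no leakage), the top k kept, a classifier
## fitted and the held-out 10% predicted, so every gene is predicted exactly
## once per iteration. 50 iterations are aggregated per gene by majority
## vote (strictly > 50% "repressed", ties fall to the nonrepressed majority
## class).
##
## Seeds: iteration seed = base_seed + iteration; the fold assignment and
## classifier seeds derive from it and NOT from the selector, so two
## selectors choosing the same top-k set on a fold provably produce the same
## fit (which run_chromatin_code exploits via memoisation).
## ---------------------------------------------------------------------------

SELECTORS <- c("info_gain", "symmetrical_uncertainty", "chi_square", "relief")
CLASSIFIERS <- c("random_forest", "naive_bayes", "knn", "svm")
POSITIVE_CLASS <- "repressed"

#' Configuration for the classification procedure
#'
#' @param selectors feature-selection algorithms to run.
#' @param classifiers classifiers to run.
#' @param top_k number of top-ranked features used by the classifiers.
#' @param n_folds cross-validation folds (stratified by class).
#' @param n_iterations repeated CV iterations aggregated by vote.
#' @param vote_threshold strict fraction of repressed votes required for an
#'   aggregate repressed call.
#' @param base_seed seed from which all iteration seeds derive.
#' @return list of class \code{ml_config}.
#' @export
ml_config <- function(selectors = SELECTORS, classifiers = CLASSIFIERS,
                      top_k = 20, n_folds = 10, n_iterations = 50,
                      vote_threshold = 0.5, base_seed = 1) {
  selectors <- match.arg(selectors, SELECTORS, several.ok = TRUE)
  classifiers <- match.arg(classifiers, CLASSIFIERS, several.ok = TRUE)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (top_k < 1) stop("top_k must be >= 1")
  structure(list(selectors = selectors, classifiers = classifiers,
                 top_k = top_k, n_folds = n_folds,
                 n_iterations = n_iterations,
                 vote_threshold = vote_threshold, base_seed = base_seed),
            class = "ml_config")
}

## --------------------------- feature scoring ------------------------------

## Equal-frequency discretization into at most n_bins levels; features with
## few distinct values keep them as-is.
discretize_ef <- function(x, n_bins = 10) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 1))
  br <- br[-c(1, length(br))]
  as.integer(cut(x, breaks = c(-Inf, br, Inf)))
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

info_gain_score <- function(x_disc, y) {
  hy <- entropy_bits(y)
  cond <- tapply(seq_along(y), x_disc, function(i) {
    length(i) / length(y) * entropy_bits(y[i])
  })
  hy - sum(cond)
}

su_score <- function(x_disc, y) {
  ig <- info_gain_score(x_disc, y)
  hx <- entropy_bits(x_disc); hy <- entropy_bits(y)
  if (hx + hy == 0) return(0)
  2 * ig / (hx + hy)
}

chi_square_score <- function(x_disc, y) {
  tab <- table(x_disc, y)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

## ReliefF with two classes: k nearest hits and misses per instance over all
## instances, Manhattan distance on range-normalized features.
relief_scores <- function(X, y, k = 10) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  diag(D) <- Inf
  w <- numeric(p)
  same <- outer(y, y, "==")
  for (i in seq_len(n)) {
    hits <- which(same[i, ]); hits <- hits[hits != i]
    misses <- which(!same[i, ])
    if (!length(hits) || !length(misses)) next
    kh <- hits[order(D[i, hits])[seq_len(min(k, length(hits)))]]
    km <- misses[order(D[i, misses])[seq_len(min(k, length(misses)))]]
    dh <- abs(sweep(Xn[kh, , drop = FALSE], 2, Xn[i, ]))
    dm <- abs(sweep(Xn[km, , drop = FALSE], 2, Xn[i, ]))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w / n
}

#' Rank features by one selection algorithm
#'
#' \code{info_gain}, \code{symmetrical_uncertainty} and \code{chi_square}
#' discretize continuous features into (at most) 10 equal-frequency bins;
#' \code{relief} is ReliefF with 10 neighbors over all instances. All four
#' are deterministic given their input.
#'
#' @param table feature table with a \code{label} column.
#' @param method one of the four selector names.
#' @param n_bins discretization bins for the contingency-based selectors.
#' @param relief_k neighbor count for ReliefF.
#' @return data.frame \code{feature}, \code{score}, sorted decreasing.
#' @export
rank_features <- function(table, method = SELECTORS, n_bins = 10,
                          relief_k = 10) {
  method <- match.arg(method)
  feats <- feature_columns(table)
  y <- table$label
  if (length(unique(y)) < 2) stop("label column is constant; cannot rank")
  scores <- if (method == "relief") {
    relief_scores(as.matrix(table[feats]), y, k = relief_k)
  } else {
    vapply(feats, function(f) {
      xd <- discretize_ef(table[[f]], n_bins)
      switch(method,
             info_gain = info_gain_score(xd, y),
             symmetrical_uncertainty = su_score(xd, y),
             chi_square = chi_square_score(xd, y))
    }, numeric(1))
  }
  out <- data.frame(feature = feats, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$feature), , drop = FALSE]
}

## Rank features for several selectors at once, sharing the per-feature
## discretization across the three contingency-based selectors. Produces
## exactly the same orderings as repeated rank_features calls.
rank_features_multi <- function(table, selectors, top_k, n_bins = 10,
                                relief_k = 10) {
  feats <- feature_columns(table)
  y <- table$label
  cont <- intersect(selectors, c("info_gain", "symmetrical_uncertainty",
                                 "chi_square"))
  scores <- list()
  if (length(cont)) {
    hy <- entropy_bits(y)
    per_feat <- vapply(feats, function(f) {
      xd <- discretize_ef(table[[f]], n_bins)
      tab <- table(xd, y)
      n <- sum(tab)
      rs <- rowSums(tab)
      hcond <- sum(vapply(seq_len(nrow(tab)), function(i) {
        p <- tab[i, ] / rs[i]
        rs[i] / n * (-sum(p[p > 0] * log2(p[p > 0])))
      }, numeric(1)))
      ig <- hy - hcond
      px <- rs / n
      hx <- -sum(px[px > 0] * log2(px[px > 0]))
      su <- if (hx + hy == 0) 0 else 2 * ig / (hx + hy)
      chi <- if (nrow(tab) < 2 || ncol(tab) < 2) 0 else {
        e <- outer(rs, colSums(tab)) / n
        sum((tab - e)^2 / e)
      }
      c(info_gain = ig, symmetrical_uncertainty = su, chi_square = chi)
    }, numeric(3))
    for (s in cont) scores[[s]] <- per_feat[s, ]
  }
  if ("relief" %in% selectors)
    scores[["relief"]] <- relief_scores(as.matrix(table[feats]), y,
                                        k = relief_k)
  lapply(scores[selectors], function(sc) {
    ord <- order(-sc, feats)
    feats[ord][seq_len(min(top_k, length(feats)))]
  })
}

## ----------------------------- classifiers --------------------------------

fit_predict <- function(classifier, xtr, ytr, xte, seed) {
  ytr <- factor(ytr, levels = c("nonrepressed", "repressed"))
  switch(classifier,
    random_forest = {
      fit <- ranger::ranger(x = xtr, y = ytr, num.trees = 100,
                            num.threads = 1, seed = seed, verbose = FALSE)
      as.character(predict(fit, xte, num.threads = 1,
                           verbose = FALSE)$predictions)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      ## variance floor: a class-constant feature must not yield a
      ## degenerate density
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6 * max(1, max(abs(tb[, 1]))))
        tb
      })
      as.character(predict(fit, xte))
    },
    knn = {
      mu <- colMeans(xtr)
      s <- apply(xtr, 2, sd); s[s == 0] <- 1
      tr <- scale(xtr, mu, s); te <- scale(xte, mu, s)
      set.seed(seed)
      as.character(class::knn(tr, te, ytr, k = 5))
    },
    svm = {
      keep <- apply(xtr, 2, function(col) sd(col) > 0)
      if (!any(keep)) keep[1] <- TRUE
      fit <- e1071::svm(xtr[, keep, drop = FALSE], ytr, kernel = "linear",
                        cost = 1, scale = TRUE)
      as.character(predict(fit, xte[, keep, drop = FALSE]))
    },
    stop("unknown classifier: ", classifier))
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

iteration_seed <- function(base_seed, iter) {
  (base_seed + iter) %% .Machine$integer.max
}

classifier_seed <- function(base_seed, iter, fold) {
  ((base_seed + iter) * 1009 + fold) %% .Machine$integer.max
}

#' One cross-validated selection + classification iteration
#'
#' Stratified folds; per fold, features are ranked on the training part
#' only, the top \code{top_k} kept, the classifier fitted and the held-out
#' part predicted. Deterministic given \code{seed}.
#'
#' @param table feature table (\code{gene_id}, features, \code{label}).
#' @param selector selector name.
#' @param classifier classifier name.
#' @param top_k features kept per fold.
#' @param n_folds folds.
#' @param seed iteration seed.
#' @return named character vector: predicted class per gene.
#' @export
run_iteration <- function(table, selector, classifier, top_k = 20,
                          n_folds = 10, seed = 1) {
  set.seed(seed)
  folds <- stratified_folds(table$label, n_folds)
  preds <- character(nrow(table))
  for (f in seq_len(n_folds)) {
    tr <- table[folds != f, , drop = FALSE]
    te <- table[folds == f, , drop = FALSE]
    if (length(unique(tr$label)) < 2)
      stop("a class is absent from training fold ", f)
    ranking <- rank_features(tr, selector)
    top <- ranking$feature[seq_len(min(top_k, nrow(ranking)))]
    preds[folds == f] <- fit_predict(classifier,
                                     as.matrix(tr[top]), tr$label,
                                     as.matrix(te[top]),
                                     classifier_seed(seed - 1, 1, f))
  }
  names(preds) <- table$gene_id
  preds
}

## ------------------------- aggregation & reports --------------------------

#' Aggregate per-iteration votes into per-gene calls
#'
#' @param votes matrix (genes x iterations) of predicted classes, rownames
#'   = gene ids; no missing entries allowed.
#' @param vote_threshold a gene is called repressed iff its repressed vote
#'   fraction strictly exceeds this (ties fall to nonrepressed).
#' @return data.frame: \code{gene_id}, \code{vote_fraction} (repressed),
#'   \code{aggregate_class}.
#' @export
aggregate_predictions <- function(votes, vote_threshold = 0.5) {
  if (anyNA(votes)) stop("missing iteration predictions")
  frac <- rowMeans(votes == POSITIVE_CLASS)
  data.frame(gene_id = rownames(votes), vote_fraction = frac,
             aggregate_class = ifelse(frac > vote_threshold, "repressed",
                                      "nonrepressed"),
             stringsAsFactors = FALSE)
}

#' Evaluate aggregate calls against true labels
#'
#' Accuracies are percentages. \code{baseline_overall} is the majority-class
#' rate truncated to an integer for report display; \code{baseline_repressed}
#' is the repressed-class prevalence.
#'
#' @param records output of \code{\link{aggregate_predictions}}.
#' @param labels named character vector (or vector aligned with records) of
#'   true labels.
#' @return list: \code{overall}, \code{repressed}, \code{nonrepressed}
#'   accuracies (percent), \code{baseline_overall} (integer percent),
#'   \code{baseline_repressed} (percent).
#' @export
evaluate <- function(records, labels) {
  if (!is.null(names(labels))) labels <- labels[records$gene_id]
  correct <- records$aggregate_class == labels
  pct <- function(x) 100 * mean(x)
  list(overall = pct(correct),
       repressed = pct(correct[labels == "repressed"]),
       nonrepressed = pct(correct[labels == "nonrepressed"]),
       baseline_overall = trunc(100 * max(table(labels)) / length(labels)),
       baseline_repressed = 100 * mean(labels == "repressed"))
}

#' Run the full selection x classification grid
#'
#' For every (selector, classifier) combination: \code{n_iterations}
#' stratified cross-validated runs, majority-vote aggregation and
#' evaluation. Classifier fits are memoised across selectors within an
#' iteration/fold when the selected top-k feature sets coincide (seeds are
#' selector-independent, so the memoised fit is exactly the fit that
#' standalone \code{\link{run_iteration}} would produce).
#'
#' @param table feature table.
#' @param config an \code{\link{ml_config}}.
#' @return object of class \code{chromcode_fit}: \code{votes} (per combo,
#'   genes x iterations matrix), \code{records} (per combo), and
#'   \code{evaluation} (one row per combo with accuracy percentages).
#' @export
run_chromatin_code <- function(table, config = ml_config()) {
  combos <- expand.grid(selector = config$selectors,
                        classifier = config$classifiers,
                        stringsAsFactors = FALSE)
  gid <- table$gene_id
  votes <- lapply(seq_len(nrow(combos)), function(i)
    matrix(NA_character_, length(gid), config$n_iterations,
           dimnames = list(gid, NULL)))
  names(votes) <- paste(combos$selector, combos$classifier, sep = ".")

  for (iter in seq_len(config$n_iterations)) {
    iseed <- iteration_seed(config$base_seed, iter)
    set.seed(iseed)
    folds <- stratified_folds(table$label, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- table[folds != f, , drop = FALSE]
      te <- table[folds == f, , drop = FALSE]
      if (length(unique(tr$label)) < 2)
        stop("a class is absent from training fold ", f)
      cseed <- classifier_seed(config$base_seed, iter, f)
      rankings <- rank_features_multi(tr, config$selectors, config$top_k)
      xtr <- as.matrix(tr[feature_columns(tr)])
      xte <- as.matrix(te[feature_columns(te)])
      fit_cache <- new.env(parent = emptyenv())
      for (ci in seq_len(nrow(combos))) {
        top <- rankings[[combos$selector[ci]]]
        key <- paste(combos$classifier[ci],
                     paste(sort(top), collapse = ","), sep = "|")
        pred <- if (!is.null(fit_cache[[key]])) fit_cache[[key]]
        else {
          p <- fit_predict(combos$classifier[ci], xtr[, top, drop = FALSE],
                           tr$label, xte[, top, drop = FALSE], cseed)
          fit_cache[[key]] <- p
          p
        }
        votes[[ci]][folds == f, iter] <- pred
      }
    }
  }

  records <- lapply(votes, aggregate_predictions,
                    vote_threshold = config$vote_threshold)
  labels <- setNames(table$label, table$gene_id)
  ev <- do.call(rbind, lapply(seq_len(nrow(combos)), function(ci) {
    e <- evaluate(records[[ci]], labels)
    data.frame(selector = combos$selector[ci],
               classifier = combos$classifier[ci],
               overall = e$overall, repressed = e$repressed,
               nonrepressed = e$nonrepressed,
               baseline_overall = e$baseline_overall,
               baseline_repressed = e$baseline_repressed,
               stringsAsFactors = FALSE)
  }))
  structure(list(votes = votes, records = records, evaluation = ev,
                 labels = labels, config = config),
            class = "chromcode_fit")
}

#' @export
print.chromcode_fit <- function(x, ...) {
  cat(sprintf("chromcode_fit: %d selector x classifier combination(s), %d genes\n",
              nrow(x$evaluation), length(x$labels)))
  print(x$evaluation, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-gene prediction report across all method combinations
#'
#' One row per gene (optionally a subset), one column per
#' selector/classifier combination holding the aggregate call, plus the
#' true label and the number of combinations that called the gene
#' correctly. Useful for spotting genes miscalled by every method.
#'
#' @param fit a \code{chromcode_fit}.
#' @param gene_subset optional character vector of gene ids.
#' @return data.frame report.
#' @export
prediction_report <- function(fit, gene_subset = NULL) {
  genes <- if (is.null(gene_subset)) names(fit$labels) else gene_subset
  out <- data.frame(gene_id = genes, label = unname(fit$labels[genes]),
                    stringsAsFactors = FALSE)
  for (combo in names(fit$records)) {
    rec <- fit$records[[combo]]
    out[[combo]] <- rec$aggregate_class[match(genes, rec$gene_id)]
  }
  calls <- as.matrix(out[, names(fit$records), drop = FALSE])
  out$n_correct <- rowSums(calls == out$label)
  out[seq_len(nrow(out)), , drop = FALSE]
}
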
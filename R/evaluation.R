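#' Cross-validation fold plan with negative sampling
#'
#' Partitions the labeled positives uniformly at random into `k` folds whose
#' sizes differ by at most 1, and samples `negative_ratio` negatives per
#' positive for each fold, uniformly without replacement from the unlabeled
#' microbe-drug pairs (never overlapping the positives, nor each other across
#' folds).
#'
#' @param positives A data.frame whose first two columns are microbe and drug
#'   ids of the labeled associations.
#' @param k Number of folds (e.g. 5 or 10).
#' @param registry A [node_registry()] defining the microbe x drug universe.
#' @param seed Seed; the plan is reproducible given it.
#' @param negative_ratio Negatives sampled per positive (default 1).
#' @param negative_exclude Optional data.frame of additional (microbe, drug)
#'   pairs barred from the negative universe — e.g. the planted ground truth
#'   in simulation studies, or externally suspected associations.
#' @return An object of class `fold_plan`: `positives` and `negatives`
#'   data.frames with a `fold` column, plus `k` and `seed`.
#' @export
make_folds <- function(positives, k, registry, seed = 1, negative_ratio = 1,
                       negative_exclude = NULL) {
  pos <- data.frame(microbe = trimws(as.character(positives[[1]])),
                    drug = trimws(as.character(positives[[2]])))
  n <- nrow(pos)
  if (n < k) stop("fewer positives than folds")
  set.seed(derive_seed(seed, 11, 0))
  idx <- sample.int(n)
  fold <- integer(n)
  fold[idx] <- rep_len(seq_len(k), n)
  pos$fold <- fold

  universe_key <- function(m, d) paste(m, d, sep = "\r")
  banned <- universe_key(pos$microbe, pos$drug)
  if (!is.null(negative_exclude)) {
    banned <- c(banned, universe_key(trimws(as.character(negative_exclude[[1]])),
                                     trimws(as.character(negative_exclude[[2]]))))
  }
  all_pairs <- expand.grid(microbe = registry$microbes, drug = registry$drugs,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  free <- !(universe_key(all_pairs$microbe, all_pairs$drug) %in% banned)
  pool <- all_pairs[free, , drop = FALSE]
  need_per_fold <- round(negative_ratio * tabulate(fold, k))
  need <- sum(need_per_fold)
  if (nrow(pool) < need) {
    stop(sprintf("only %d unlabeled pairs available for %d negatives",
                 nrow(pool), need))
  }
  take <- pool[sample.int(nrow(pool), need), , drop = FALSE]
  take$fold <- rep.int(seq_len(k), need_per_fold)
  rownames(take) <- NULL
  structure(list(positives = pos, negatives = take, k = k, seed = seed),
            class = "fold_plan")
}

# Tie-aware AUROC via the rank statistic (Mann-Whitney).
auroc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Tie-aware AUPR by step integration of the precision-recall curve: ties are
# processed as blocks of equal score, precision evaluated at each block end.
aupr_step <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  blocks <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  n_pos <- sum(y)
  last_of_block <- which(diff(c(blocks, Inf)) != 0)
  tp_b <- tp[last_of_block]
  k_b <- last_of_block
  prec <- tp_b / k_b
  rec <- tp_b / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for scored pairs
#'
#' AUROC is computed from the rank statistic (tie-aware; all-equal scores
#' give 0.5), AUPR by step integration of the precision-recall curve, and
#' accuracy, precision, recall and F1 from the confusion counts obtained by
#' thresholding the scores (`score >= threshold` predicts an association).
#' Precision (and hence F1) is 0 when nothing is predicted positive.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `metric_report`: `auroc`, `aupr`, `acc`,
#'   `precision`, `recall`, `f1` and the confusion counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; AUROC/AUPR undefined")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(auroc = auroc_rank(scores, labels),
                 aupr = aupr_step(scores, labels),
                 acc = (tp + tn) / (tp + tn + fp + fn),
                 precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUROC %.4f | AUPR %.4f | ACC %.4f | F1 %.4f (TP %d FP %d TN %d FN %d)\n",
              x$auroc, x$aupr, x$acc, x$f1, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Cross-validated end-to-end evaluation
#'
#' For each fold: rebuild the GIP similarities from the training positives
#' only, reassemble the graph (metabolite-side edge sets and functional
#' similarities are fold-invariant), fit the edge-type transition matrix,
#' walk, embed, train the classifier on training positives plus the other
#' folds' negatives, and score the held-out positives and the fold's
#' negatives. No test positive influences any training-time quantity.
#'
#' @param data A list with elements `registry`, `sm_edges`, `mm_edges`,
#'   `dm_edges`, `positives` (labeled pair data.frame), and optionally
#'   `microbe_functional`, `drug_functional` (similarity matrices) and
#'   `negative_exclude` (see [make_folds()]). [synth_generate()] returns this
#'   shape directly.
#' @param k Number of folds (default 5).
#' @param seed Master seed for folds, walks, embeddings and the classifier.
#' @param alpha Similarity threshold gating same-type edges (default 0.65).
#' @param walk A [walk_config()] (its seed is overridden per fold).
#' @param em List of EM options: `iterations`, `trial_walks`, `trial_length`.
#' @param embed List of skip-gram options: `dim`, `window`, `negatives`,
#'   `epochs`, `learning_rate`.
#' @param classifier List: `method`, `n_trees`.
#' @param negative_ratio Negatives per positive (default 1).
#' @param refit_gip Recompute GIP-from-associations per training fold
#'   (default TRUE; disabling it leaks test labels and is only provided for
#'   ablation).
#' @param threshold Decision threshold for ACC/F1 (default 0.5).
#' @return A list of class `cv_report`: `folds` (per-fold `metric_report`s),
#'   `summary` (per-fold metric data.frame) and `means`.
#' @export
run_cv <- function(data, k = 5, seed = 1, alpha = 0.65,
                   walk = walk_config(), em = list(), embed = list(),
                   classifier = list(), negative_ratio = 1, refit_gip = TRUE,
                   threshold = 0.5) {
  em <- utils::modifyList(list(iterations = 5, trial_walks = 10,
                               trial_length = 10), em)
  embed <- utils::modifyList(list(dim = 1024, window = 9, negatives = 5,
                                  epochs = 5, learning_rate = 0.025), embed)
  classifier <- utils::modifyList(list(method = "xgboost", n_trees = 564),
                                  classifier)
  reg <- data$registry
  plan <- make_folds(data$positives, k, reg, seed = seed,
                     negative_ratio = negative_ratio,
                     negative_exclude = data$negative_exclude)
  sm_mat <- edge_profile_matrix(data$sm_edges, reg, "sm")
  dm_mat <- edge_profile_matrix(data$dm_edges, reg, "dm")
  gip_sm <- if (any(sm_mat > 0)) gip_similarity(sm_mat, "rows") else NULL
  gip_dm <- if (any(dm_mat > 0)) gip_similarity(dm_mat, "rows") else NULL

  folds <- vector("list", k)
  for (t in seq_len(k)) {
    train_pos <- plan$positives[plan$positives$fold != t, c("microbe", "drug")]
    test_pos <- plan$positives[plan$positives$fold == t, c("microbe", "drug")]
    train_neg <- plan$negatives[plan$negatives$fold != t, c("microbe", "drug")]
    test_neg <- plan$negatives[plan$negatives$fold == t, c("microbe", "drug")]
    I <- association_matrix(
      if (refit_gip) train_pos else data$positives[, 1:2],
      reg, "training-fold")
    gip_im <- gip_similarity(I, "rows")
    gip_id <- gip_similarity(I, "cols")
    msim <- microbe_similarity(gip_assoc = gip_im, gip_metabolite = gip_sm,
                               genomic = data$microbe_functional)
    dsim <- drug_similarity(gip_assoc = gip_id, gip_metabolite = gip_dm,
                            fingerprint = data$drug_functional)
    graph <- assemble_graph(reg, data$sm_edges, data$mm_edges, data$dm_edges,
                            microbe_sim = msim, drug_sim = dsim, alpha = alpha)
    fold_seed <- derive_seed(seed, 101, t)
    cfg <- walk
    cfg$seed <- fold_seed
    M <- transition_em_fit(graph, cfg, iterations = em$iterations,
                           trial_walks = em$trial_walks,
                           trial_length = em$trial_length,
                           seed = derive_seed(seed, 103, t))
    corpus <- generate_corpus(graph, M, cfg)
    emb <- train_embeddings(corpus, dim = embed$dim, window = embed$window,
                            negatives = embed$negatives, epochs = embed$epochs,
                            learning_rate = embed$learning_rate,
                            seed = derive_seed(seed, 107, t))
    train_feats <- pair_features(
      emb, rbind(train_pos, train_neg),
      labels = rep(c(1L, 0L), c(nrow(train_pos), nrow(train_neg))))
    model <- train_classifier(train_feats, method = classifier$method,
                              n_trees = classifier$n_trees,
                              seed = derive_seed(seed, 109, t))
    test_feats <- pair_features(
      emb, rbind(test_pos, test_neg),
      labels = rep(c(1L, 0L), c(nrow(test_pos), nrow(test_neg))))
    scores <- predict(model, test_feats)
    folds[[t]] <- compute_metrics(scores, test_feats$label, threshold)
    folds[[t]]$scores <- scores
    folds[[t]]$pairs <- rbind(test_pos, test_neg)
    folds[[t]]$graph_edge_counts <- vapply(graph$edges, nrow, 0L)
    folds[[t]]$I <- I
  }
  metric_names <- c("auroc", "aupr", "acc", "precision", "recall", "f1")
  summary <- as.data.frame(t(vapply(folds, function(f)
    unlist(f[metric_names]), numeric(length(metric_names)))))
  means <- colMeans(summary)
  structure(list(folds = folds, summary = summary, means = means,
                 plan = plan, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV means: AUROC %.4f | AUPR %.4f | ACC %.4f | F1 %.4f\n",
              x$k, x$means["auroc"], x$means["aupr"], x$means["acc"],
              x$means["f1"]))
  invisible(x)
}
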
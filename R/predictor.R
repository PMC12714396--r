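#' Hadamard pair features
#'
#' The feature vector of a (microbe, drug) pair is the element-wise product
#' of the two node embeddings, `d_uv[j] = z_u[j] * z_v[j]`; the operation is
#' symmetric in the pair. Pairs with a missing embedding are skipped and
#' reported via the `skipped` element.
#'
#' @param embeddings An `embedding_table` (matrix with id rownames).
#' @param pairs A data.frame whose first two columns are microbe and drug ids.
#' @param labels Optional 0/1 labels aligned with `pairs`.
#' @return A list of class `pair_features`: `microbe`, `drug`, `x` (feature
#'   matrix), `label` (or `NULL`), `skipped` (data.frame of dropped pairs).
#' @export
pair_features <- function(embeddings, pairs, labels = NULL) {
  m <- trimws(as.character(pairs[[1]]))
  d <- trimws(as.character(pairs[[2]]))
  if (!is.null(labels) && length(labels) != length(m)) {
    stop("labels must align with pairs")
  }
  have <- m %in% rownames(embeddings) & d %in% rownames(embeddings)
  skipped <- data.frame(microbe = m[!have], drug = d[!have])
  if (nrow(skipped) > 0) {
    message(nrow(skipped), " pair(s) skipped for missing embeddings")
  }
  x <- embeddings[m[have], , drop = FALSE] * embeddings[d[have], , drop = FALSE]
  rownames(x) <- NULL
  structure(list(microbe = m[have], drug = d[have], x = unclass(x),
                 label = if (is.null(labels)) NULL else labels[have],
                 skipped = skipped),
            class = "pair_features")
}

#' Train the association classifier
#'
#' Gradient-boosted trees (the default; `K` trees with the binary logistic
#' loss and the library's default per-tree regularization) on Hadamard pair
#' features. `"logistic"` and `"random_forest"` are drop-in alternates behind
#' the same interface for ablation.
#'
#' @param features A [pair_features()] object with labels, or a feature
#'   matrix (then `labels` is required).
#' @param labels 0/1 vector when `features` is a matrix.
#' @param method `"xgboost"` (default), `"logistic"`, or `"random_forest"`.
#' @param n_trees Number of boosting rounds / trees, `K` (default 564).
#' @param seed Seed; single-threaded training is deterministic given it.
#' @param params Extra parameters passed to the underlying learner.
#' @return An object of class `mda_model`.
#' @export
train_classifier <- function(features, labels = NULL,
                             method = c("xgboost", "logistic", "random_forest"),
                             n_trees = 564, seed = 1, params = list()) {
  method <- match.arg(method)
  if (inherits(features, "pair_features")) {
    labels <- features$label
    features <- features$x
  }
  if (is.null(labels)) stop("labels are required for training")
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  stopifnot(n_trees >= 1)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- switch(method,
    xgboost = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(features, label = y)
      xgboost::xgb.train(
        params = utils::modifyList(
          list(objective = "binary:logistic", nthread = 1, seed = seed,
               verbosity = 0),
          params),
        data = dtrain, nrounds = n_trees)
    },
    logistic = {
      df <- data.frame(y = y, features)
      stats::glm(y ~ ., data = df, family = stats::binomial())
    },
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("method 'random_forest' requires the randomForest package")
      }
      set.seed(seed)
      randomForest::randomForest(features, factor(y, levels = c(0, 1)),
                                 ntree = n_trees)
    })
  structure(list(method = method, fit = fit, n_trees = n_trees, seed = seed,
                 dim = ncol(features)),
            class = "mda_model")
}

#' @export
print.mda_model <- function(x, ...) {
  cat(sprintf("mda_model: %s, %d tree(s)/round(s), %d features\n",
              x$method, x$n_trees, x$dim))
  invisible(x)
}

#' Predict association probabilities
#'
#' @param object An `mda_model`.
#' @param newdata A [pair_features()] object or a feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.mda_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pair_features")) newdata$x else newdata
  if (ncol(x) != object$dim) stop("feature dimension mismatch")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- switch(object$method,
    xgboost = stats::predict(object$fit, xgboost::xgb.DMatrix(x)),
    logistic = stats::predict(object$fit, data.frame(x), type = "response"),
    random_forest = stats::predict(object$fit, x, type = "prob")[, "1"])
  as.numeric(p)
}

#' Rank candidate partners for a query node
#'
#' Scores every candidate against the query and returns them in descending
#' score order (ties broken by node id for stability). The query only needs
#' an embedding, not labeled associations, so nodes present in the graph but
#' absent from the labeled data receive a full ranking.
#'
#' @param model An `mda_model`.
#' @param embeddings An `embedding_table`.
#' @param query A drug id (to rank microbes) or microbe id (to rank drugs).
#' @param candidates Character vector of candidate partner ids; candidates
#'   without embeddings are dropped.
#' @param exclude Character vector of partner ids to omit (e.g. already-known
#'   associations of the query).
#' @param top Optional integer limiting the output length.
#' @return A data.frame `rank`, `query`, `candidate`, `score`.
#' @export
rank_candidates <- function(model, embeddings, query, candidates,
                            exclude = NULL, top = NULL) {
  query <- trimws(query)
  if (!query %in% rownames(embeddings)) {
    stop("query node '", query, "' has no embedding")
  }
  candidates <- setdiff(trimws(candidates), c(trimws(exclude), query))
  candidates <- candidates[candidates %in% rownames(embeddings)]
  if (length(candidates) == 0) {
    return(data.frame(rank = integer(), query = character(),
                      candidate = character(), score = numeric()))
  }
  feats <- pair_features(embeddings,
                         data.frame(a = candidates,
                                    b = rep(query, length(candidates))))
  score <- predict(model, feats)
  o <- order(-score, candidates)
  out <- data.frame(rank = seq_along(o), query = query,
                    candidate = candidates[o], score = score[o])
  if (!is.null(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}

#' Write predictions to a TSV
#'
#' @param pairs A data.frame with microbe and drug columns.
#' @param scores Numeric scores aligned with `pairs`.
#' @param path Output path (`microbe<TAB>drug<TAB>score`).
#' @export
save_predictions <- function(pairs, scores, path) {
  utils::write.table(
    data.frame(microbe = pairs[[1]], drug = pairs[[2]],
               score = sprintf("%.17g", scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
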
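#' Train node embeddings with type-aware skip-gram
#'
#' Skip-gram with negative sampling over the walk corpus, where for each
#' (center, context) pair the negative nodes are drawn only from the node
#' type of the context node, using per-type `unigram^0.75` noise
#' distributions. This keeps the contrastive signal within a type, so
#' microbes, metabolites and drugs land on a comparable scale. Training is
#' single-threaded and reproducible given the seed; only the input (center)
#' vectors are exported.
#'
#' @param corpus A [generate_corpus()] result (or [load_corpus()]).
#' @param dim Embedding dimension (default 1024).
#' @param window Context window size (default 9).
#' @param negatives Negative samples per positive pair (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param learning_rate Initial learning rate, linearly decayed (default 0.025).
#' @param min_count Minimum corpus frequency for a node to receive a vector
#'   (default 1).
#' @param seed Seed for initialization and sampling.
#' @return A numeric matrix (nodes x dim) with node ids as rownames and a
#'   `meta` attribute recording the training parameters; class
#'   `embedding_table`.
#' @export
train_embeddings <- function(corpus, dim = 1024, window = 9, negatives = 5,
                             epochs = 5, learning_rate = 0.025, min_count = 1,
                             seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"), dim >= 1, window >= 1,
            negatives >= 0, epochs >= 1)
  if (length(corpus$sentences) == 0) stop("empty corpus")
  tokens <- unlist(corpus$sentences, use.names = FALSE)
  if (length(unique(tokens)) < 2 || !any(lengths(corpus$sentences) >= 2)) {
    stop("corpus has no (center, context) pairs to train on")
  }
  n <- length(corpus$node_ids)
  emb <- .sgns_train(lapply(corpus$sentences, as.integer),
                     as.integer(corpus$node_types), as.integer(n),
                     as.integer(dim), as.integer(window),
                     as.integer(negatives), as.integer(epochs),
                     learning_rate, as.integer(min_count), as.double(seed))
  rownames(emb) <- corpus$node_ids
  freq <- tabulate(tokens, n)
  emb <- emb[freq >= min_count, , drop = FALSE]
  if (any(!is.finite(emb))) stop("non-finite embedding values")
  attr(emb, "meta") <- list(dim = dim, window = window, negatives = negatives,
                            epochs = epochs, learning_rate = learning_rate,
                            min_count = min_count, seed = seed)
  class(emb) <- c("embedding_table", class(emb))
  emb
}

#' Save / load embeddings in word2vec text format
#'
#' First line `N d`, then one `id v1 ... vd` line per node. The text
#' round-trip preserves ids exactly and vectors to within 1e-6.
#'
#' @param embeddings An `embedding_table` (matrix with id rownames).
#' @param path Output file.
#' @export
save_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(embeddings), ncol(embeddings)), con)
  for (i in seq_len(nrow(embeddings))) {
    writeLines(paste(rownames(embeddings)[i],
                     paste(sprintf("%.8g", embeddings[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path)
  header <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(header) != 2 || anyNA(header)) stop("malformed word2vec header")
  n <- header[1]; d <- header[2]
  if (length(lines) != n + 1L) {
    stop(sprintf("header declares %d vectors but file has %d lines of data",
                 n, length(lines) - 1L))
  }
  ids <- character(n)
  emb <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]]
    if (length(parts) != d + 1L) stop("vector length mismatch at line ", i + 1L)
    ids[i] <- parts[1]
    emb[i, ] <- as.numeric(parts[-1])
  }
  rownames(emb) <- ids
  class(emb) <- c("embedding_table", class(emb))
  emb
}
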
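#' Random walk configuration
#'
#' The walker starts `walks_per_node` walks from every node (all three types)
#' and extends each to `walk_length` nodes, i.e. `walk_length - 1`
#' transitions, truncating early only at dead ends. At microbe/drug nodes the
#' gate `rho(v) = f(S_v^max)` with the steep sigmoid
#' `f(x) = 1 / (1 + exp(-k (x - t)))` decides between a same-type move
#' (mass `rho`, proportional to similarity) and a metabolite move (mass
#' `1 - rho`, proportional to edge weight). At metabolite nodes the move is
#' biased by the edge-type transition matrix.
#'
#' @param walks_per_node Walks started per node (default 100).
#' @param walk_length Walk length counted in nodes (default 10).
#' @param k Sigmoid steepness (default 100).
#' @param t Sigmoid midpoint in (0, 1) (default 0.85).
#' @param w_default Weight assigned to unweighted edges (default 1).
#' @param alpha_pq Normalization factor of the transition laws (constant 1).
#' @param seed Master seed; per-walk streams are derived from it together
#'   with the node and walk indices, so corpora are order-independent.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(walks_per_node = 100, walk_length = 10, k = 100,
                        t = 0.85, w_default = 1, alpha_pq = 1, seed = 1) {
  stopifnot(walks_per_node >= 1, walk_length >= 2, t > 0, t < 1, k > 0)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length), k = k, t = t,
                 w_default = w_default, alpha_pq = alpha_pq,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Sigmoid gate of the walk model
#'
#' `f(x) = 1 / (1 + exp(-k (x - t)))`; with the default steepness `k = 100`
#' and midpoint `t = 0.85`, `f` is close to 1 for `x > t` and close to 0 for
#' `x < t`.
#'
#' @param x Similarity value(s).
#' @param k Steepness.
#' @param t Midpoint.
#' @export
sigmoid_gate <- function(x, k = 100, t = 0.85) 1 / (1 + exp(-k * (x - t)))

# Derive a per-stream seed below 2^31 from (master, a, b) with two Lehmer
# steps; exact in double arithmetic (products stay below 2^53).
derive_seed <- function(master, a = 0, b = 0) {
  m <- 2147483647
  s <- as.double(master) %% m
  s <- (s * 48271 + as.double(a)) %% m
  s <- (s * 48271 + as.double(b)) %% m
  as.integer(s)
}

#' Same-type gate probability rho(v)
#'
#' For a microbe or drug node `v`, let `T` be the number of its metabolite
#' edges. `rho(v) = 1` when `T = 0` (the walker can only move among same-type
#' neighbors); otherwise `rho(v) = f(S_v^max)` where `S_v^max` is the highest
#' similarity among `v`'s same-type graph neighbors (the weight of its
#' strongest ss/dd edge), and `rho(v) = 0` when `v` has metabolite edges but
#' no same-type neighbor.
#'
#' @param graph A `hetero_graph`.
#' @param v A microbe or drug node id.
#' @param cfg A [walk_config()] (provides `k` and `t`).
#' @return A single number in \[0, 1\].
#' @export
rho <- function(graph, v, cfg = walk_config()) {
  tp <- node_type(graph$registry, trimws(v))
  if (is.na(tp)) stop("unknown node id: ", v)
  if (tp == "metabolite") stop("rho is defined for microbe and drug nodes only")
  nb <- graph_neighbors(graph, v)
  rho_from_neighbors(nb$edge_type %in% c("ss", "dd"),
                     nb$edge_type %in% c("sm", "dm"), nb$weight, cfg)
}

rho_from_neighbors <- function(same, met, w, cfg) {
  if (sum(met) == 0) return(1)
  if (sum(same) == 0) return(0)
  sigmoid_gate(max(w[same]), cfg$k, cfg$t)
}

#' Transition law at a metabolite node
#'
#' Probability of stepping from metabolite `v` (reached from `u`) to each
#' neighbor `n`, proportional to
#' `w_vn * M[Q(u, v), Q(v, n)] * alpha_pq`. At a walk start (`u = NULL`) the
#' edge-type factor is 1 for all candidates.
#'
#' @param graph A `hetero_graph`.
#' @param M An edge-type transition matrix ([transition_init()] /
#'   [transition_em_fit()]).
#' @param u Previous node id, or `NULL` at a walk start.
#' @param v Current metabolite node id.
#' @param cfg A [walk_config()].
#' @return A data.frame `id`, `node_type`, `edge_type`, `prob` over the
#'   neighbors of `v` (probabilities sum to 1), with zero rows if `v` is
#'   isolated (the walk truncates).
#' @export
metabolite_step_probs <- function(graph, M, u = NULL, v, cfg = walk_config()) {
  tp <- node_type(graph$registry, trimws(v))
  if (is.na(tp) || tp != "metabolite") stop("v must be a metabolite node")
  nb <- graph_neighbors(graph, v)
  if (is.null(u)) {
    fac <- rep(1, nrow(nb))
  } else {
    q_in <- edge_type(graph, u, v)
    if (is.na(q_in)) stop("u must be adjacent to v")
    fac <- M[q_in, nb$edge_type]
  }
  if (nrow(nb) == 0) return(cbind(nb, prob = numeric()))
  p <- nb$weight * fac * cfg$alpha_pq
  nb$prob <- p / sum(p)
  nb
}

#' Transition law at a microbe/drug node
#'
#' Total mass `rho(v)` goes to same-type neighbors proportionally to their
#' similarity (the ss/dd edge weight), and mass `1 - rho(v)` to metabolite
#' neighbors proportionally to the (unit) edge weight. When one side is
#' empty, `rho`'s conventions place all mass on the other.
#'
#' @param graph A `hetero_graph`.
#' @param v Current microbe or drug node id.
#' @param cfg A [walk_config()].
#' @return A data.frame `id`, `node_type`, `edge_type`, `prob` over the
#'   neighbors of `v`; zero rows if `v` has no neighbors at all.
#' @export
typed_step_probs <- function(graph, v, cfg = walk_config()) {
  tp <- node_type(graph$registry, trimws(v))
  if (is.na(tp)) stop("unknown node id: ", v)
  if (tp == "metabolite") stop("typed_step_probs applies to microbe/drug nodes")
  nb <- graph_neighbors(graph, v)
  if (nrow(nb) == 0) return(cbind(nb, prob = numeric()))
  same <- nb$edge_type %in% c("ss", "dd")
  met <- nb$edge_type %in% c("sm", "dm")
  r <- rho_from_neighbors(same, met, nb$weight, cfg)
  p <- numeric(nrow(nb))
  if (any(same)) p[same] <- r * nb$weight[same] / sum(nb$weight[same])
  # metabolite side: w_vn over the alpha_pq-normalizer, i.e. the neighbor count
  if (any(met)) p[met] <- (1 - r) * nb$weight[met] / (cfg$w_default * sum(met))
  nb$prob <- p / sum(p)
  nb
}

# Internal walker: per-node sampling tables.
#  - microbe/drug nodes: one cumulative distribution (independent of the
#    previous node since alpha_pq is constant).
#  - metabolite nodes: one cumulative distribution per incoming edge type
#    (columns: none, ss, sm, mm, dm, dd).
build_walker <- function(graph, M = NULL, cfg = walk_config()) {
  if (is.null(M)) M <- transition_init()
  reg <- graph$registry
  N <- n_nodes(reg)
  types <- registry_types(reg)
  adj <- build_adjacency(graph)
  tabs <- vector("list", N)
  for (g in seq_len(N)) {
    a <- adj[[g]]
    n <- length(a$nbr)
    if (n == 0) next  # tabs[[g]] stays NULL: dead end, walks truncate
    if (types[g] == 2L) {  # metabolite: columns indexed by incoming type + 1
      cum <- matrix(0, n, 6L)
      base <- a$w * cfg$alpha_pq
      cum[, 1] <- cumsum(base / sum(base))
      for (q in 1:5) {
        p <- base * M[q, a$et]
        cum[, q + 1L] <- cumsum(p / sum(p))
      }
    } else {
      same <- a$et %in% c(1L, 5L)
      met <- a$et %in% c(2L, 4L)
      r <- rho_from_neighbors(same, met, a$w, cfg)
      p <- numeric(n)
      if (any(same)) p[same] <- r * a$w[same] / sum(a$w[same])
      if (any(met)) p[met] <- (1 - r) * a$w[met] / (cfg$w_default * sum(met))
      s <- sum(p)
      if (s <= 0) next
      cum <- cumsum(p / s)
    }
    tabs[[g]] <- list(nbr = a$nbr, et = a$et, cum = cum)
  }
  list(tabs = tabs, types = types, N = N)
}

# One walk from global node `start`; R's RNG must already be seeded.
# Returns list(nodes, etypes) of global indices / edge-type codes.
walk_one <- function(walker, start, walk_length) {
  nodes <- integer(walk_length)
  etypes <- integer(walk_length - 1L)
  nodes[1] <- start
  q_in <- 0L
  len <- 1L
  cur <- start
  while (len < walk_length) {
    tab <- walker$tabs[[cur]]
    if (is.null(tab)) break
    cum <- if (is.matrix(tab$cum)) tab$cum[, q_in + 1L] else tab$cum
    u <- stats::runif(1)
    idx <- findInterval(u, cum) + 1L
    if (idx > length(tab$nbr)) idx <- length(tab$nbr)
    len <- len + 1L
    nodes[len] <- tab$nbr[idx]
    etypes[len - 1L] <- tab$et[idx]
    q_in <- tab$et[idx]
    cur <- tab$nbr[idx]
  }
  list(nodes = nodes[seq_len(len)], etypes = etypes[seq_len(len - 1L)])
}

# Run walks_per_node walks from every node. Returns sentences (list of global
# index vectors) and the per-walk edge-type count matrix (n_walks x 5).
simulate_walks <- function(walker, cfg, seed_salt = 0L) {
  N <- walker$N
  wpn <- cfg$walks_per_node
  sentences <- vector("list", N * wpn)
  counts <- matrix(0L, N * wpn, 5L)
  row <- 0L
  for (g in seq_len(N)) {
    for (w in seq_len(wpn)) {
      row <- row + 1L
      set.seed(derive_seed(cfg$seed + seed_salt, g, w))
      wk <- walk_one(walker, g, cfg$walk_length)
      sentences[[row]] <- wk$nodes
      if (length(wk$etypes)) counts[row, ] <- tabulate(wk$etypes, 5L)
    }
  }
  list(sentences = sentences, counts = counts)
}

#' Generate a walk corpus
#'
#' Starts `cfg$walks_per_node` seeded walks from every node of the graph and
#' records the visited node sequences. Isolated nodes yield length-1 walks;
#' truncated walks are kept (the skip-gram trainer handles short sentences).
#'
#' @param graph A `hetero_graph`.
#' @param M Edge-type transition matrix; `NULL` for the uniform prior (under
#'   which the metabolite-node law reduces to weight-only normalization).
#' @param cfg A [walk_config()].
#' @return An object of class `walk_corpus`: `sentences` (list of integer
#'   vectors of global node indices), `node_ids`, `node_types`, `cfg`.
#' @export
generate_corpus <- function(graph, M = NULL, cfg = walk_config()) {
  walker <- build_walker(graph, M, cfg)
  sim <- simulate_walks(walker, cfg)
  structure(list(sentences = sim$sentences,
                 node_ids = registry_ids(graph$registry),
                 node_types = registry_types(graph$registry),
                 cfg = cfg),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks over %d nodes (max length %d)\n",
              length(x$sentences), length(x$node_ids),
              max(lengths(x$sentences))))
  invisible(x)
}

#' Save / load a walk corpus
#'
#' One walk per line of space-separated node ids (word2vec sentence format),
#' with a sidecar `<path>.types.tsv` mapping node ids to node types.
#'
#' @param corpus A `walk_corpus`.
#' @param path Output text file.
#' @export
save_corpus <- function(corpus, path) {
  lines <- vapply(corpus$sentences,
                  function(s) paste(corpus$node_ids[s], collapse = " "), "")
  writeLines(lines, path)
  utils::write.table(
    data.frame(id = corpus$node_ids, type = NODE_TYPES[corpus$node_types]),
    paste0(path, ".types.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(path) {
  lines <- readLines(path)
  nodes <- utils::read.delim(paste0(path, ".types.tsv"), colClasses = "character")
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  sentences <- lapply(strsplit(lines, " ", fixed = TRUE),
                      function(s) unname(idx[s]))
  if (anyNA(unlist(sentences))) stop("corpus references ids absent from sidecar")
  structure(list(sentences = sentences, node_ids = nodes$id,
                 node_types = match(nodes$type, NODE_TYPES),
                 cfg = NULL),
            class = "walk_corpus")
}
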
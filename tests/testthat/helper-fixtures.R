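# Shared fixtures and independent oracles.

# A small hand-built graph: 2 microbes, 3 metabolites, 2 drugs.
#   m1-c1, m1-c2, m2-c2 (sm); c1-c2, c2-c3 (mm); d1-c2, d2-c3 (dm)
# plus similarity-gated ss/dd edges when sims are supplied.
tiny_registry <- function() {
  node_registry(c("m1", "m2"), c("c1", "c2", "c3"), c("d1", "d2"))
}

tiny_graph <- function(microbe_sim = NULL, drug_sim = NULL, alpha = 0.65) {
  reg <- tiny_registry()
  sm <- edge_table(c("m1", "m1", "m2"), c("c1", "c2", "c2"), "sm", reg)
  mm <- edge_table(c("c1", "c2"), c("c2", "c3"), "mm", reg)
  dm <- edge_table(c("d1", "d2"), c("c2", "c3"), "dm", reg)
  assemble_graph(reg, sm, mm, dm, microbe_sim, drug_sim, alpha = alpha)
}

sim_matrix <- function(ids, values) {
  S <- matrix(values, length(ids), length(ids), dimnames = list(ids, ids))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# Random small graph for property sweeps: 2-4 nodes per type, random
# metabolite edges, random similarity matrices.
random_small_graph <- function(seed) {
  set.seed(seed)
  ns <- sample(2:4, 1); nm <- sample(2:4, 1); nd <- sample(2:4, 1)
  reg <- node_registry(paste0("s", seq_len(ns)), paste0("c", seq_len(nm)),
                       paste0("d", seq_len(nd)))
  rand_bipartite <- function(a, b, kind, p = 0.5) {
    idx <- which(matrix(runif(length(a) * length(b)) < p,
                        length(a), length(b)) == 1, arr.ind = TRUE)
    edge_table(a[idx[, 1]], b[idx[, 2]], kind, reg)
  }
  rand_sim <- function(ids) {
    S <- matrix(runif(length(ids)^2), length(ids), length(ids))
    sim_matrix(ids, S)
  }
  assemble_graph(reg,
                 rand_bipartite(reg$microbes, reg$metabolites, "sm"),
                 rand_bipartite(reg$metabolites, reg$metabolites, "mm", 0.4),
                 rand_bipartite(reg$drugs, reg$metabolites, "dm"),
                 rand_sim(reg$microbes), rand_sim(reg$drugs), alpha = 0.5)
}

# Brute-force Tanimoto over two bit-position sets.
bf_tanimoto <- function(a, b) {
  u <- length(unique(c(a, b)))
  if (u == 0) return(0)
  sum(a %in% b) / u
}

# Brute-force patristic distances: breadth-first path sums over the tree's
# edge list, independent of ape's cophenetic code path.
bf_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(start) {
    d <- rep(NA_real_, nodes)
    d[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        nb <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (is.na(d[nb])) { d[nb] <- d[v] + w; queue <- c(queue, nb) }
      }
    }
    d
  }
  D <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) D[i, ] <- dist_from(i)[seq_len(n_tip)]
  D
}

# Brute-force Mann-Whitney AUROC: pairwise comparisons with half-credit ties.
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Extract consecutive (node type, node type) transitions from a corpus.
corpus_transitions <- function(corpus) {
  do.call(rbind, lapply(corpus$sentences, function(s) {
    if (length(s) < 2) return(NULL)
    cbind(corpus$node_types[s[-length(s)]], corpus$node_types[s[-1]])
  }))
}

# Quick small synthetic dataset for pipeline-level tests.
small_synth <- function(seed = 3, ...) {
  synth_generate(synth_config(n_microbes = 12, n_metabolites = 14,
                              n_drugs = 12, n_groups = 2, sim_noise = 0.05,
                              seed = seed, ...))
}
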
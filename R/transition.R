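#' Uniform edge-type transition matrix
#'
#' The 5x5 matrix coupling the incoming and outgoing edge types of a step at
#' a metabolite node, initialized to all ones (under which the metabolite-node
#' transition law reduces to weight-only normalization).
#'
#' @return A 5x5 matrix with dimnames `ss, sm, mm, dm, dd`.
#' @export
transition_init <- function() {
  matrix(1, 5, 5, dimnames = list(EDGE_TYPES, EDGE_TYPES))
}

validate_transition <- function(M) {
  if (!is.matrix(M) || !identical(dim(M), c(5L, 5L))) {
    stop("M must be a 5x5 matrix")
  }
  if (is.null(rownames(M))) dimnames(M) <- list(EDGE_TYPES, EDGE_TYPES)
  if (any(!is.finite(M)) || any(M <= 0)) stop("M entries must be positive and finite")
  if (max(abs(M - t(M))) > 1e-12) stop("M must be symmetric")
  M
}

# Pearson correlation with the zero-variance convention cor = 0.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Fit the edge-type transition matrix by EM over trial walks
#'
#' Alternates between generating trial walks under the current matrix
#' (E-step; the full walker with both node-type strategies) and re-estimating
#' each entry from the per-walk edge-type count vectors (M-step):
#' `M[i, j] = sigmoid(cor(counts_i, counts_j))` with `sigmoid(x) =
#' 1 / (1 + exp(-x))`, so entries stay in (0, 1) and the matrix stays
#' symmetric by construction. Edge types absent from the graph keep their
#' prior value; a zero-variance count vector yields correlation 0 and hence
#' an entry of 0.5.
#'
#' @param graph A `hetero_graph`.
#' @param cfg A [walk_config()] providing the gate parameters.
#' @param iterations Number of EM iterations (default 5).
#' @param trial_walks Trial walks per node per iteration (default 10).
#' @param trial_length Trial walk length in nodes (default 10).
#' @param seed Seed; the fit is fully reproducible given it.
#' @return A 5x5 edge-type transition matrix with attribute `iterations`.
#' @export
transition_em_fit <- function(graph, cfg = walk_config(), iterations = 5,
                              trial_walks = 10, trial_length = 10, seed = 1) {
  stopifnot(iterations >= 1)
  if (sum(vapply(graph$edges, nrow, 0L)) == 0) stop("graph has no edges")
  M <- transition_init()
  present <- which(vapply(graph$edges[EDGE_TYPES], nrow, 0L) > 0)
  absent <- setdiff(1:5, present)
  if (length(absent)) {
    message("edge type(s) absent from graph keep prior transition weights: ",
            paste(EDGE_TYPES[absent], collapse = ", "))
  }
  trial_cfg <- walk_config(walks_per_node = trial_walks,
                           walk_length = trial_length, k = cfg$k, t = cfg$t,
                           w_default = cfg$w_default, alpha_pq = cfg$alpha_pq,
                           seed = seed)
  for (it in seq_len(iterations)) {
    walker <- build_walker(graph, M, trial_cfg)
    sim <- simulate_walks(walker, trial_cfg, seed_salt = it * 7919L)
    C <- sim$counts
    for (a in present) {
      for (b in present) {
        if (b < a) next
        M[a, b] <- M[b, a] <- 1 / (1 + exp(-safe_cor(C[, a], C[, b])))
      }
    }
  }
  attr(M, "iterations") <- iterations
  validate_transition(M)
}

#' Save / load an edge-type transition matrix
#'
#' CSV with edge-type labels on both axes.
#'
#' @param M A 5x5 edge-type transition matrix.
#' @param path CSV file path.
#' @export
save_transition <- function(M, path) {
  utils::write.csv(validate_transition(M), path, quote = FALSE)
  invisible(path)
}

#' @rdname save_transition
#' @export
load_transition <- function(path) {
  M <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  validate_transition(M[EDGE_TYPES, EDGE_TYPES])
}
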
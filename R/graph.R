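#' @useDynLib mmdwalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The five edge types of the heterogeneous graph. Integer codes used
# throughout the walker follow this order.
EDGE_TYPES <- c("ss", "sm", "mm", "dm", "dd")
NODE_TYPES <- c("microbe", "metabolite", "drug")

#' Node registry for the microbe-metabolite-drug graph
#'
#' Holds the ordered id lists of the three node types and provides the
#' node-type lookup used everywhere else. Ids are whitespace-trimmed and must
#' be unique across all three lists (the type lookup must be a function).
#'
#' @param microbes,metabolites,drugs Character vectors of node ids.
#' @return An object of class `node_registry`.
#' @export
node_registry <- function(microbes = character(), metabolites = character(),
                          drugs = character()) {
  microbes <- trimws(as.character(microbes))
  metabolites <- trimws(as.character(metabolites))
  drugs <- trimws(as.character(drugs))
  for (ids in list(microbes, metabolites, drugs)) {
    if (anyDuplicated(ids)) {
      stop("duplicate node ids within a type: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    if (any(!nzchar(ids))) stop("empty node id")
  }
  all_ids <- c(microbes, metabolites, drugs)
  if (anyDuplicated(all_ids)) {
    stop("node ids shared across types: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  structure(list(microbes = microbes, metabolites = metabolites, drugs = drugs),
            class = "node_registry")
}

#' @export
print.node_registry <- function(x, ...) {
  cat(sprintf("node_registry: %d microbes, %d metabolites, %d drugs\n",
              length(x$microbes), length(x$metabolites), length(x$drugs)))
  invisible(x)
}

n_nodes <- function(registry) {
  length(registry$microbes) + length(registry$metabolites) + length(registry$drugs)
}

# All ids in global order (microbes, then metabolites, then drugs).
registry_ids <- function(registry) {
  c(registry$microbes, registry$metabolites, registry$drugs)
}

registry_types <- function(registry) {
  rep.int(1:3, c(length(registry$microbes), length(registry$metabolites),
                 length(registry$drugs)))
}

#' Look up node types
#'
#' @param registry A [node_registry()].
#' @param ids Character vector of node ids.
#' @return Character vector with entries `"microbe"`, `"metabolite"`,
#'   `"drug"`, or `NA` for unknown ids.
#' @export
node_type <- function(registry, ids) {
  NODE_TYPES[registry_types(registry)[match(ids, registry_ids(registry))]]
}

# Type-local 1-based index of ids that are known to be of type `type`.
type_index <- function(registry, ids, type) {
  pool <- switch(type, microbe = registry$microbes,
                 metabolite = registry$metabolites, drug = registry$drugs)
  match(ids, pool)
}

# Global 1-based index across the concatenated id list.
global_index <- function(registry, ids) {
  match(ids, registry_ids(registry))
}

edge_endpoint_types <- function(kind) {
  switch(kind,
         ss = c("microbe", "microbe"), sm = c("microbe", "metabolite"),
         mm = c("metabolite", "metabolite"), dm = c("drug", "metabolite"),
         dd = c("drug", "drug"))
}

# Canonicalize an edge data.frame (columns i, j, w): drop self loops for
# within-type sets, enforce i < j there, deduplicate.
canonical_edges <- function(df, kind) {
  if (nrow(df) == 0) {
    return(data.frame(i = integer(), j = integer(), w = numeric()))
  }
  if (kind %in% c("ss", "mm", "dd")) {
    keep <- df$i != df$j
    df <- df[keep, , drop = FALSE]
    swap <- df$i > df$j
    tmp <- df$i[swap]; df$i[swap] <- df$j[swap]; df$j[swap] <- tmp
  }
  df <- df[!duplicated(df[c("i", "j")]), , drop = FALSE]
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load a two-column edge table
#'
#' Reads a TSV with header `source<TAB>target` describing microbe-metabolite
#' (`sm`), metabolite-metabolite (`mm`) or drug-metabolite (`dm`) edges. Edges
#' are deduplicated and given weight 1. Rows naming ids absent from the
#' registry are dropped, collected in the `"dropped"` attribute and reported
#' via a message — the registry is the single source of truth.
#'
#' @param path Path to the TSV file.
#' @param kind One of `"sm"`, `"mm"`, `"dm"`.
#' @param registry A [node_registry()].
#' @return A data.frame with integer columns `i`, `j` (type-local indices;
#'   for cross-type edges `i` indexes the microbe/drug, `j` the metabolite)
#'   and `w` (all 1), with attribute `dropped`.
#' @export
load_edge_table <- function(path, kind = c("sm", "mm", "dm"), registry) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE)
  if (ncol(raw) != 2) {
    stop(sprintf("edge table '%s': expected 2 columns, found %d", path, ncol(raw)))
  }
  bad <- which(!nzchar(trimws(raw[[1]])) | !nzchar(trimws(raw[[2]])))
  if (length(bad)) {
    stop(sprintf("edge table '%s': malformed row at line %d", path, bad[1] + 1L))
  }
  if (nrow(raw) == 0) warning(sprintf("edge table '%s' is empty", path))
  edge_table(trimws(raw[[1]]), trimws(raw[[2]]), kind, registry)
}

#' Build an edge set from id vectors
#'
#' In-memory counterpart of [load_edge_table()]; used by the simulator and by
#' callers that already hold id pairs.
#'
#' @param source,target Character vectors of node ids.
#' @inheritParams load_edge_table
#' @return See [load_edge_table()].
#' @export
edge_table <- function(source, target, kind = c("sm", "mm", "dm"), registry) {
  kind <- match.arg(kind)
  types <- edge_endpoint_types(kind)
  i <- type_index(registry, source, types[1])
  j <- type_index(registry, target, types[2])
  known <- !is.na(i) & !is.na(j)
  dropped <- data.frame(source = source[!known], target = target[!known])
  if (nrow(dropped) > 0) {
    message(sprintf("%d %s edge(s) referenced unknown ids and were dropped", nrow(dropped), kind))
  }
  df <- canonical_edges(data.frame(i = i[known], j = j[known],
                                   w = rep(1, sum(known))), kind)
  attr(df, "dropped") <- dropped
  df
}

#' Binary microbe x drug association matrix
#'
#' @param pairs A data.frame whose first two columns are microbe and drug ids.
#' @param registry A [node_registry()].
#' @param provenance `"full"` or `"training-fold"` (which associations the
#'   matrix reflects; GIP similarities in cross-validation must come from
#'   training folds only).
#' @return A binary matrix with microbe ids as rownames and drug ids as
#'   colnames, attribute `provenance`, and attribute `dropped` listing pairs
#'   naming unknown ids.
#' @export
association_matrix <- function(pairs, registry, provenance = c("full", "training-fold")) {
  provenance <- match.arg(provenance)
  m <- trimws(as.character(pairs[[1]]))
  d <- trimws(as.character(pairs[[2]]))
  i <- type_index(registry, m, "microbe")
  j <- type_index(registry, d, "drug")
  known <- !is.na(i) & !is.na(j)
  dropped <- data.frame(microbe = m[!known], drug = d[!known])
  if (nrow(dropped) > 0) {
    message(sprintf("%d association(s) referenced unknown ids and were dropped", nrow(dropped)))
  }
  I <- matrix(0L, length(registry$microbes), length(registry$drugs),
              dimnames = list(registry$microbes, registry$drugs))
  I[cbind(i[known], j[known])] <- 1L
  attr(I, "provenance") <- provenance
  attr(I, "dropped") <- dropped
  I
}

#' Load a microbe-drug association table
#'
#' TSV with header `microbe<TAB>drug`, one labeled association per row.
#'
#' @inheritParams load_edge_table
#' @inheritParams association_matrix
#' @return See [association_matrix()].
#' @export
load_association_table <- function(path, registry, provenance = c("full", "training-fold")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(raw) != 2) stop(sprintf("association table '%s': expected 2 columns", path))
  association_matrix(data.frame(microbe = raw[[1]], drug = raw[[2]]),
                     registry, provenance)
}

# Dense binary matrix view of an sm/dm edge set (rows = microbes or drugs).
edge_profile_matrix <- function(edges, registry, kind = c("sm", "dm")) {
  kind <- match.arg(kind)
  row_ids <- if (kind == "sm") registry$microbes else registry$drugs
  m <- matrix(0L, length(row_ids), length(registry$metabolites),
              dimnames = list(row_ids, registry$metabolites))
  if (nrow(edges) > 0) m[cbind(edges$i, edges$j)] <- 1L
  m
}

validate_similarity <- function(sim, ids, what, tol = 1e-12) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    stop(what, " similarity must be a square matrix")
  }
  if (!is.null(ids)) {
    if (is.null(rownames(sim))) stop(what, " similarity must carry id dimnames")
    if (!identical(rownames(sim), ids)) {
      if (!all(ids %in% rownames(sim))) stop(what, " similarity is missing ids")
      sim <- sim[ids, ids, drop = FALSE]
    }
  }
  if (max(abs(sim - t(sim))) > tol) stop(what, " similarity matrix is asymmetric")
  if (any(sim < -tol) || any(sim > 1 + tol)) {
    stop(what, " similarity entries must lie in [0, 1]")
  }
  if (nrow(sim) > 0 && max(abs(diag(sim) - 1)) > tol) {
    stop(what, " similarity diagonal must be 1")
  }
  sim
}

#' Assemble the microbe-metabolite-drug heterogeneous graph
#'
#' Metabolite-touching edge sets (`sm`, `mm`, `dm`) are copied with weight 1.
#' Microbe-microbe (`ss`) and drug-drug (`dd`) edges are created for pairs
#' whose aggregated similarity lies strictly above the threshold `alpha`, and
#' carry the similarity value as weight. Labeled microbe-drug associations are
#' never graph edges; they supervise the classifier only.
#'
#' @param registry A [node_registry()].
#' @param sm_edges,mm_edges,dm_edges Edge sets from [edge_table()] /
#'   [load_edge_table()] (data.frames with columns `i`, `j`, `w`).
#' @param microbe_sim,drug_sim Symmetric similarity matrices in \[0, 1\] with
#'   unit diagonal and id dimnames, or `NULL` for no same-type edges.
#' @param alpha Similarity threshold in \[0, 1\]; values exactly equal to
#'   `alpha` do not create an edge. Default 0.65.
#' @return An object of class `hetero_graph`.
#' @export
assemble_graph <- function(registry, sm_edges, mm_edges, dm_edges,
                           microbe_sim = NULL, drug_sim = NULL, alpha = 0.65) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  sim_edges <- function(sim, ids, what) {
    if (is.null(sim) || length(ids) == 0) {
      return(data.frame(i = integer(), j = integer(), w = numeric()))
    }
    sim <- validate_similarity(sim, ids, what)
    idx <- which(upper.tri(sim) & sim > alpha, arr.ind = TRUE)
    canonical_edges(data.frame(i = idx[, 1], j = idx[, 2], w = sim[idx]),
                    "ss")
  }
  edges <- list(
    ss = sim_edges(microbe_sim, registry$microbes, "microbe"),
    sm = canonical_edges(sm_edges, "sm"),
    mm = canonical_edges(mm_edges, "mm"),
    dm = canonical_edges(dm_edges, "dm"),
    dd = sim_edges(drug_sim, registry$drugs, "drug")
  )
  edges$sm$w <- rep(1, nrow(edges$sm))
  edges$mm$w <- rep(1, nrow(edges$mm))
  edges$dm$w <- rep(1, nrow(edges$dm))
  check_bounds <- function(df, n_i, n_j, kind) {
    if (nrow(df) > 0 && (min(df$i) < 1 || max(df$i) > n_i ||
                         min(df$j) < 1 || max(df$j) > n_j)) {
      stop("edge indices out of range for type ", kind)
    }
  }
  ns <- length(registry$microbes); nm <- length(registry$metabolites)
  nd <- length(registry$drugs)
  check_bounds(edges$ss, ns, ns, "ss"); check_bounds(edges$sm, ns, nm, "sm")
  check_bounds(edges$mm, nm, nm, "mm"); check_bounds(edges$dm, nd, nm, "dm")
  check_bounds(edges$dd, nd, nd, "dd")
  structure(list(registry = registry, edges = edges, alpha = alpha),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf(
    "hetero_graph: %d microbes, %d metabolites, %d drugs | edges: %s\n",
    length(x$registry$microbes), length(x$registry$metabolites),
    length(x$registry$drugs),
    paste(sprintf("%s=%d", EDGE_TYPES, vapply(x$edges[EDGE_TYPES], nrow, 0L)),
          collapse = " ")))
  invisible(x)
}

# Long-form directed view of all edges: each undirected/bipartite edge appears
# once per direction. Columns: src, dst (global indices), w, et (1..5).
graph_edge_list <- function(graph) {
  reg <- graph$registry
  ns <- length(reg$microbes); nm <- length(reg$metabolites)
  off <- c(microbe = 0L, metabolite = ns, drug = ns + nm)
  pieces <- lapply(seq_along(EDGE_TYPES), function(k) {
    kind <- EDGE_TYPES[k]
    df <- graph$edges[[kind]]
    if (nrow(df) == 0) return(NULL)
    tp <- edge_endpoint_types(kind)
    a <- df$i + off[[tp[1]]]
    b <- df$j + off[[tp[2]]]
    data.frame(src = c(a, b), dst = c(b, a), w = c(df$w, df$w),
               et = rep.int(k, 2L * nrow(df)))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(src = integer(), dst = integer(),
                                      w = numeric(), et = integer())
  out
}

# Adjacency lists indexed by global node index; neighbors ordered by global
# index (i.e. by node type, then type-local index) for determinism.
build_adjacency <- function(graph) {
  N <- n_nodes(graph$registry)
  el <- graph_edge_list(graph)
  adj <- rep(list(list(nbr = integer(), w = numeric(), et = integer())), N)
  if (nrow(el) > 0) {
    o <- order(el$src, el$dst)
    el <- el[o, ]
    grp <- split(seq_len(nrow(el)), el$src)
    for (s in names(grp)) {
      rows <- grp[[s]]
      adj[[as.integer(s)]] <- list(nbr = el$dst[rows], w = el$w[rows],
                                   et = el$et[rows])
    }
  }
  adj
}

#' Neighbors of a node
#'
#' Reports all graph neighbors of a node in deterministic order (by node type,
#' then index), with edge weights and edge types. Undirected edges are visible
#' from both endpoints.
#'
#' @param graph A [assemble_graph()] result.
#' @param id A node id.
#' @param type_filter Optional node type (`"microbe"`, `"metabolite"`,
#'   `"drug"`) restricting the result; e.g. `type_filter = "metabolite"` on a
#'   microbe returns exactly its microbe-metabolite partners, and filtering to
#'   the node's own type gives its same-type neighbor set.
#' @return A data.frame with columns `id`, `node_type`, `edge_type`, `weight`.
#' @export
graph_neighbors <- function(graph, id, type_filter = NULL) {
  reg <- graph$registry
  g <- global_index(reg, trimws(id))
  if (length(g) != 1 || is.na(g)) stop("unknown node id: ", id)
  a <- build_adjacency(graph)[[g]]
  ids <- registry_ids(reg)[a$nbr]
  tp <- NODE_TYPES[registry_types(reg)[a$nbr]]
  out <- data.frame(id = ids, node_type = tp, edge_type = EDGE_TYPES[a$et],
                    weight = a$w, stringsAsFactors = FALSE)
  if (!is.null(type_filter)) {
    type_filter <- match.arg(type_filter, NODE_TYPES)
    out <- out[out$node_type == type_filter, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Edge type of a stored edge
#'
#' @param graph A `hetero_graph`.
#' @param u,v Node ids.
#' @return One of `"ss"`, `"sm"`, `"mm"`, `"dm"`, `"dd"`, or `NA` if `(u, v)`
#'   is not an edge.
#' @export
edge_type <- function(graph, u, v) {
  nb <- graph_neighbors(graph, u)
  hit <- nb$edge_type[nb$id == trimws(v)]
  if (length(hit) == 0) NA_character_ else hit
}

#' Serialize / load a heterogeneous graph
#'
#' Writes `nodes.tsv` (`id`, `type`) and `edges.tsv` (`source`, `target`,
#' `type`, `weight` with 17 significant digits) into a directory. The
#' round-trip reproduces edge sets with bit-equal weights.
#'
#' @param graph A `hetero_graph`.
#' @param dir Directory path (created if missing).
#' @return `save_graph` returns `dir` invisibly; `load_graph` returns the
#'   reconstructed `hetero_graph`.
#' @export
save_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- graph$registry
  nodes <- data.frame(id = registry_ids(reg),
                      type = NODE_TYPES[registry_types(reg)])
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rows <- lapply(EDGE_TYPES, function(kind) {
    df <- graph$edges[[kind]]
    if (nrow(df) == 0) return(NULL)
    tp <- edge_endpoint_types(kind)
    src_ids <- switch(tp[1], microbe = reg$microbes, metabolite = reg$metabolites,
                      drug = reg$drugs)
    dst_ids <- switch(tp[2], microbe = reg$microbes, metabolite = reg$metabolites,
                      drug = reg$drugs)
    data.frame(source = src_ids[df$i], target = dst_ids[df$j], type = kind,
               weight = sprintf("%.17g", df$w))
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        type = character(), weight = character())
  }
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("alpha\t%.17g", graph$alpha), file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname save_graph
#' @export
load_graph <- function(dir) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"), colClasses = "character")
  reg <- node_registry(nodes$id[nodes$type == "microbe"],
                       nodes$id[nodes$type == "metabolite"],
                       nodes$id[nodes$type == "drug"])
  edges <- utils::read.delim(file.path(dir, "edges.tsv"), colClasses = "character")
  meta <- utils::read.delim(file.path(dir, "meta.tsv"), header = FALSE)
  sets <- lapply(EDGE_TYPES, function(kind) {
    df <- edges[edges$type == kind, , drop = FALSE]
    tp <- edge_endpoint_types(kind)
    canonical_edges(data.frame(i = type_index(reg, df$source, tp[1]),
                               j = type_index(reg, df$target, tp[2]),
                               w = as.numeric(df$weight)), kind)
  })
  names(sets) <- EDGE_TYPES
  g <- assemble_graph(reg, sets$sm, sets$mm, sets$dm, alpha = as.numeric(meta[1, 2]))
  g$edges$ss <- sets$ss
  g$edges$dd <- sets$dd
  g
}
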
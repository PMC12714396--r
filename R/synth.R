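#' Configuration for the planted-partition simulator
#'
#' Microbes, metabolites and drugs are assigned to latent groups; a microbe
#' (or drug) gains an edge to a metabolite with probability `p_in` when they
#' share a group and `p_out` otherwise, so same-group microbes and drugs are
#' coupled through shared metabolites — the metabolite-mediation mechanism
#' the predictor is meant to recover. A (microbe, drug) pair is a planted
#' ground-truth association iff the two share a group; a stated fraction of
#' the planted pairs is observed as labels, the rest is held-out truth.
#'
#' @param n_microbes,n_metabolites,n_drugs Node counts (defaults 30/40/30).
#' @param n_groups Number of latent groups (default 3).
#' @param p_in,p_out Within/between-group metabolite edge probabilities
#'   (defaults 0.5 / 0.02); recoverability requires `p_in > p_out`, and
#'   `p_in = p_out` is the null control.
#' @param mm_density Erdos-Renyi density of metabolite-metabolite
#'   reaction-pair edges (default 0.05).
#' @param sim_noise Gaussian noise s.d. added to the similarity matrices
#'   (default 0.05).
#' @param labeled_fraction Fraction of planted pairs observed as labels
#'   (default 0.5).
#' @param seed Seed; generation is bit-reproducible given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_microbes = 30, n_metabolites = 40, n_drugs = 30,
                         n_groups = 3, p_in = 0.5, p_out = 0.02,
                         mm_density = 0.05, sim_noise = 0.05,
                         labeled_fraction = 0.5, seed = 1) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            mm_density >= 0, mm_density <= 1,
            labeled_fraction > 0, labeled_fraction <= 1,
            n_groups >= 1, n_microbes >= n_groups, n_drugs >= n_groups)
  structure(list(n_microbes = n_microbes, n_metabolites = n_metabolites,
                 n_drugs = n_drugs, n_groups = n_groups, p_in = p_in,
                 p_out = p_out, mm_density = mm_density,
                 sim_noise = sim_noise, labeled_fraction = labeled_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Balanced random group assignment; never leaves a group empty when
# n >= n_groups (guarded regeneration kept for odd configurations).
assign_groups <- function(n, n_groups) {
  for (attempt in 1:100) {
    g <- sample(rep_len(seq_len(n_groups), n))
    if (length(unique(g)) == n_groups) return(g)
    message("empty group; regenerating assignment")
  }
  stop("could not assign non-empty groups")
}

# Similarity from binary metabolite profiles: affinely mapped Pearson
# correlation of profile rows plus Gaussian noise, clipped to [0, 1]. Carries
# group signal exactly insofar as the planted edges do, so the p_in = p_out
# null control is faithful.
profile_similarity <- function(P, noise_sd) {
  n <- nrow(P)
  C <- suppressWarnings(stats::cor(t(P)))
  C[!is.finite(C)] <- 0
  S <- 0.5 + 0.5 * C + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- dimnames(P)[c(1, 1)]
  S
}

#' Generate a synthetic microbe-metabolite-drug dataset
#'
#' Returns inputs in the exact shape the graph assembly and the
#' cross-validation harness consume, alongside the planted ground truth.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_data` with `registry`, `sm_edges`,
#'   `mm_edges`, `dm_edges`, `microbe_functional`, `drug_functional`
#'   (similarity matrices), `positives` (the labeled planted pairs),
#'   `truth` (all planted pairs), `negative_exclude` (= `truth`), `groups`
#'   (per-type assignments) and `cfg`.
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  reg <- node_registry(sprintf("microbe_%03d", seq_len(cfg$n_microbes)),
                       sprintf("metabolite_%03d", seq_len(cfg$n_metabolites)),
                       sprintf("drug_%03d", seq_len(cfg$n_drugs)))
  gs <- assign_groups(cfg$n_microbes, cfg$n_groups)
  gm <- assign_groups(cfg$n_metabolites, cfg$n_groups)
  gd <- assign_groups(cfg$n_drugs, cfg$n_groups)

  bipartite <- function(g_row, g_col) {
    p <- ifelse(outer(g_row, g_col, "=="), cfg$p_in, cfg$p_out)
    matrix(stats::runif(length(p)) < p, nrow(p), ncol(p)) * 1L
  }
  SM <- bipartite(gs, gm)
  DM <- bipartite(gd, gm)
  dimnames(SM) <- list(reg$microbes, reg$metabolites)
  dimnames(DM) <- list(reg$drugs, reg$metabolites)
  MM <- matrix(0L, cfg$n_metabolites, cfg$n_metabolites)
  up <- which(upper.tri(MM))
  MM[up] <- (stats::runif(length(up)) < cfg$mm_density) * 1L

  mat_edges <- function(mat, row_ids, col_ids, kind) {
    idx <- which(mat == 1L, arr.ind = TRUE)
    edge_table(row_ids[idx[, 1]], col_ids[idx[, 2]], kind, reg)
  }
  sm_edges <- mat_edges(SM, reg$microbes, reg$metabolites, "sm")
  dm_edges <- mat_edges(DM, reg$drugs, reg$metabolites, "dm")
  mm_edges <- mat_edges(MM, reg$metabolites, reg$metabolites, "mm")

  microbe_functional <- profile_similarity(SM, cfg$sim_noise)
  drug_functional <- profile_similarity(DM, cfg$sim_noise)

  planted <- expand.grid(microbe = reg$microbes, drug = reg$drugs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  planted <- planted[gs[match(planted$microbe, reg$microbes)] ==
                     gd[match(planted$drug, reg$drugs)], , drop = FALSE]
  rownames(planted) <- NULL
  n_lab <- max(1L, round(cfg$labeled_fraction * nrow(planted)))
  lab_idx <- sort(sample.int(nrow(planted), n_lab))
  positives <- planted[lab_idx, , drop = FALSE]
  rownames(positives) <- NULL

  structure(list(registry = reg, sm_edges = sm_edges, mm_edges = mm_edges,
                 dm_edges = dm_edges,
                 microbe_functional = microbe_functional,
                 drug_functional = drug_functional,
                 positives = positives, truth = planted,
                 negative_exclude = planted,
                 groups = list(microbe = gs, metabolite = gm, drug = gd),
                 cfg = cfg),
            class = "synth_data")
}

#' Write a synthetic dataset as loader-compatible files
#'
#' Emits the same TSV/CSV formats the real loaders consume: edge tables,
#' the labeled association table, and the two functional similarity
#' matrices.
#'
#' @param data A [synth_generate()] result.
#' @param dir Output directory (created if missing).
#' @export
save_synth <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- data$registry
  w <- function(df, ids_i, ids_j, name) {
    utils::write.table(data.frame(source = ids_i[df$i], target = ids_j[df$j]),
                       file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(data$sm_edges, reg$microbes, reg$metabolites, "microbe_metabolite.tsv")
  w(data$mm_edges, reg$metabolites, reg$metabolites, "metabolite_metabolite.tsv")
  w(data$dm_edges, reg$drugs, reg$metabolites, "drug_metabolite.tsv")
  utils::write.table(
    stats::setNames(data$positives[, 1:2], c("microbe", "drug")),
    file.path(dir, "associations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.csv(data$microbe_functional,
                   file.path(dir, "microbe_similarity.csv"), quote = FALSE)
  utils::write.csv(data$drug_functional,
                   file.path(dir, "drug_similarity.csv"), quote = FALSE)
  utils::write.table(
    data.frame(id = registry_ids(reg), type = NODE_TYPES[registry_types(reg)]),
    file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
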
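#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes `exp(-eta * ||p_i - p_j||^2)` between binary interaction profiles,
#' where the bandwidth `eta = eta_prime / mean(||p_i||^2)` is normalized by
#' the mean squared profile norm over the selected axis and `eta_prime` is
#' fixed to 1. Profiles are the rows of the matrix for microbes and the
#' columns for drugs.
#'
#' @param profile_matrix A binary interaction matrix (e.g. microbe x drug
#'   associations, or microbe x metabolite / drug x metabolite edges).
#' @param axis `"rows"` or `"cols"`: which slices are the profiles.
#' @param eta_prime Bandwidth numerator; 1 by convention.
#' @return A symmetric similarity matrix with unit diagonal, dimnames taken
#'   from the selected axis. For an all-zero matrix the bandwidth is
#'   undefined; the identity matrix is returned with a warning.
#' @export
gip_similarity <- function(profile_matrix, axis = c("rows", "cols"),
                           eta_prime = 1) {
  axis <- match.arg(axis)
  P <- as.matrix(profile_matrix)
  if (axis == "cols") P <- t(P)
  if (is.null(rownames(P))) rownames(P) <- as.character(seq_len(nrow(P)))
  sq_norms <- rowSums(P^2)
  msq <- mean(sq_norms)
  if (!is.finite(msq) || msq == 0) {
    warning("all-zero profile matrix: GIP bandwidth undefined, returning identity")
    S <- diag(nrow(P))
    dimnames(S) <- list(rownames(P), rownames(P))
    return(S)
  }
  eta <- eta_prime / msq
  # ||p_i - p_j||^2 = ||p_i||^2 + ||p_j||^2 - 2 p_i.p_j
  G <- tcrossprod(P)
  d2 <- outer(sq_norms, sq_norms, "+") - 2 * G
  d2[d2 < 0] <- 0
  S <- exp(-eta * d2)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(P), rownames(P))
  S
}

#' Fingerprint sets for drugs
#'
#' @param ids Character vector of drug ids.
#' @param bits List of integer vectors of set-bit positions (non-negative),
#'   one per drug. Empty bitsets are allowed and flagged.
#' @return An object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(ids, bits) {
  ids <- trimws(as.character(ids))
  if (length(ids) != length(bits)) stop("ids and bits differ in length")
  if (anyDuplicated(ids)) stop("duplicate drug ids")
  bits <- lapply(bits, function(b) {
    b <- sort(unique(as.integer(b)))
    if (length(b) && min(b) < 0) stop("negative bit position")
    b
  })
  names(bits) <- ids
  empty <- ids[lengths(bits) == 0]
  if (length(empty)) message(length(empty), " drug(s) have empty fingerprints")
  structure(list(ids = ids, bits = bits, empty = empty), class = "fingerprint_set")
}

#' Topological fingerprints from SMILES
#'
#' Converts canonical SMILES into fixed-length topological (atom-pair derived)
#' fingerprints via ChemmineR. Unparsable SMILES exclude the drug from this
#' similarity component; the failures are recorded in the `failed` attribute.
#'
#' @param smiles Named character vector of SMILES (names are drug ids), or a
#'   two-column data.frame `drug_id`, `smiles`.
#' @param nbits Fingerprint length in bits (default 1024).
#' @return A [fingerprint_set()] with attribute `failed`.
#' @export
smiles_fingerprints <- function(smiles, nbits = 1024) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("smiles_fingerprints requires the ChemmineR package")
  }
  if (is.data.frame(smiles)) {
    smi <- as.character(smiles[[2]])
    names(smi) <- trimws(as.character(smiles[[1]]))
    smiles <- smi
  }
  if (is.null(names(smiles))) stop("smiles must be named by drug id")
  # the most frequent atom-pair descriptors define the fingerprint bits
  fp_env <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = fp_env)
  descnames <- as.character(fp_env$apfp$AP)[seq_len(nbits)]
  ok_ids <- character(); bits <- list(); failed <- character()
  for (id in names(smiles)) {
    res <- tryCatch({
      sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles[[id]], id))
      ap <- ChemmineR::sdf2ap(sdf)
      fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
      which(fp[1, ] != 0) - 1L
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- c(failed, id)
    } else {
      ok_ids <- c(ok_ids, id)
      bits[[length(bits) + 1L]] <- res
    }
  }
  if (length(failed)) {
    message(length(failed), " SMILES failed to parse: ",
            paste(failed, collapse = ", "))
  }
  fps <- fingerprint_set(ok_ids, bits)
  attr(fps, "failed") <- failed
  fps
}

#' Tanimoto similarity matrix from fingerprints
#'
#' `T(a, b) = |A intersect B| / |A union B|` over set-bit positions. When both
#' bitsets are empty the similarity is 1 for the diagonal (identical ids) and
#' 0 otherwise.
#'
#' @param fps A [fingerprint_set()].
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  n <- length(fps$ids)
  S <- matrix(0, n, n, dimnames = list(fps$ids, fps$ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b < a) next
      inter <- length(intersect(fps$bits[[a]], fps$bits[[b]]))
      uni <- length(union(fps$bits[[a]], fps$bits[[b]]))
      S[a, b] <- S[b, a] <- if (uni == 0) 0 else inter / uni
    }
  }
  diag(S) <- 1
  S
}

#' Evolutionary similarity from a phylogeny
#'
#' Patristic distances (branch-length path sums between leaves) normalized by
#' the global maximum: `sim = 1 - d_p / max(d_p)`, so the most distant leaf
#' pair has similarity 0 and the diagonal is 1.
#'
#' @param tree A Newick file path or an [ape::read.tree()] `phylo` object.
#'   Branch lengths are required; missing lengths are treated as 0 with a
#'   warning; duplicate leaf labels are an error.
#' @return A symmetric similarity matrix over leaf labels.
#' @export
phylo_similarity <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object or Newick path")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  d <- ape::cophenetic.phylo(tree)
  maxd <- max(d)
  if (maxd <= 0) {
    warning("all patristic distances are 0; returning all-ones similarity")
    S <- matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
    return(S)
  }
  S <- 1 - d / maxd
  diag(S) <- 1
  S
}

#' Genomic similarity from a genome distance matrix
#'
#' `sim = 1 - d` for precomputed k-mer sketch (Mash-style) genome distances in
#' \[0, 1\]. An asymmetric input is symmetrized by averaging with a warning.
#'
#' @param distances A square CSV file (header row and first column carry ids)
#'   or a numeric matrix with id dimnames.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
genome_similarity <- function(distances) {
  if (is.character(distances)) {
    raw <- utils::read.csv(distances, row.names = 1, check.names = FALSE)
    distances <- as.matrix(raw)
  }
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    stop("genome distances must lie in [0, 1]")
  }
  if (max(abs(d - t(d))) > 1e-12) {
    warning("asymmetric distance matrix symmetrized by averaging")
    d <- (d + t(d)) / 2
  }
  S <- 1 - d
  diag(S) <- 1
  S
}

#' Average similarity components
#'
#' Element-wise weighted mean of similarity matrices sharing one id set. The
#' two-aspect scheme used for edge gating averages the GIP family first and
#' the functional family second, then averages the two aspects; see
#' [microbe_similarity()] and [drug_similarity()]. Components may leave ids
#' uncovered by carrying `NA` rows/columns: each entry is averaged over the
#' components where it is available (coverage reported via a message).
#'
#' @param components A non-empty list of similarity matrices with identical
#'   id dimnames (`NA` entries mark missing coverage).
#' @param weights Optional numeric weights, recycled to the component list;
#'   default equal weights.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
aggregate_similarity <- function(components, weights = NULL) {
  if (!is.list(components) || length(components) == 0) {
    stop("components must be a non-empty list of similarity matrices")
  }
  ids <- rownames(components[[1]])
  for (m in components) {
    if (!is.matrix(m) || !identical(rownames(m), ids) || !identical(colnames(m), ids)) {
      stop("all components must be matrices over the same id set")
    }
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  weights <- rep_len(weights, length(components))
  num <- matrix(0, nrow(components[[1]]), ncol(components[[1]]))
  den <- matrix(0, nrow(num), ncol(num))
  for (k in seq_along(components)) {
    m <- components[[k]]
    avail <- !is.na(m)
    num[avail] <- num[avail] + weights[k] * m[avail]
    den <- den + weights[k] * avail
  }
  if (any(den == 0)) {
    message(sum(den == 0), " entry(ies) covered by no component; set to 0")
  }
  S <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0; S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  incomplete <- colSums(den == 0)
  if (any(incomplete > 0)) {
    message(sum(incomplete > 0), " id(s) have partial component coverage")
  }
  S
}

#' Aggregate microbe similarity (two aspects)
#'
#' `mean( mean(GIP from associations, GIP from microbe-metabolite edges),
#'        mean(genomic, evolutionary) )`. Pass `NULL` for absent components;
#' each aspect averages whatever it has, and an empty aspect is dropped.
#'
#' @param gip_assoc,gip_metabolite GIP similarity matrices (or `NULL`).
#' @param genomic,evolutionary Functional similarity matrices (or `NULL`).
#' @return A similarity matrix, or `NULL` if every component is `NULL`.
#' @export
microbe_similarity <- function(gip_assoc = NULL, gip_metabolite = NULL,
                               genomic = NULL, evolutionary = NULL) {
  two_aspect_similarity(list(gip_assoc, gip_metabolite),
                        list(genomic, evolutionary))
}

#' Aggregate drug similarity (two aspects)
#'
#' `mean( mean(GIP from associations, GIP from drug-metabolite edges),
#'        fingerprint Tanimoto )`.
#'
#' @param gip_assoc,gip_metabolite GIP similarity matrices (or `NULL`).
#' @param fingerprint Tanimoto similarity matrix (or `NULL`).
#' @return A similarity matrix, or `NULL` if every component is `NULL`.
#' @export
drug_similarity <- function(gip_assoc = NULL, gip_metabolite = NULL,
                            fingerprint = NULL) {
  two_aspect_similarity(list(gip_assoc, gip_metabolite), list(fingerprint))
}

two_aspect_similarity <- function(gip_family, functional_family) {
  gip_family <- Filter(Negate(is.null), gip_family)
  functional_family <- Filter(Negate(is.null), functional_family)
  aspects <- list()
  if (length(gip_family)) aspects <- c(aspects, list(aggregate_similarity(gip_family)))
  if (length(functional_family)) {
    aspects <- c(aspects, list(aggregate_similarity(functional_family)))
  }
  if (length(aspects) == 0) return(NULL)
  aggregate_similarity(aspects)
}
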
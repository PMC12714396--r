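test_that("GIP kernel matches the closed form on the 2x2 case", {
  I <- diag(2)
  dimnames(I) <- list(c("a", "b"), c("x", "y"))
  S <- gip_similarity(I, "rows")
  expect_equal(S["a", "b"], exp(-2), tolerance = 0, ignore_attr = TRUE)
  expect_equal(diag(S), c(a = 1, b = 1))
  # columns as profiles: the drug-side computation is the same formula
  expect_equal(gip_similarity(I, "cols")["x", "y"], exp(-2))
})

test_that("GIP degenerate and invariance properties hold", {
  # identical profiles are maximally similar
  I <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0))
  expect_equal(gip_similarity(I)["a", "b"], 1)
  expect_warning(S0 <- gip_similarity(matrix(0, 3, 3)), "bandwidth undefined")
  expect_equal(unname(S0), diag(3))
  # conjugation by a profile permutation permutes the similarity matrix
  for (seed in 1:10) {
    set.seed(seed)
    I <- matrix(rbinom(30, 1, 0.4), 6, 5,
                dimnames = list(paste0("r", 1:6), NULL))
    p <- sample(6)
    expect_equal(unname(gip_similarity(I[p, ])), unname(gip_similarity(I)[p, p]))
    S <- gip_similarity(I)
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(S, t(S))
  }
})

test_that("Tanimoto matrix follows set arithmetic and its brute-force oracle", {
  fps <- fingerprint_set(c("a", "b", "c"),
                         list(c(1, 2, 3), c(2, 3, 4), c(7, 8)))
  S <- tanimoto_matrix(fps)
  expect_equal(S["a", "b"], 0.5)       # 2 shared / 4 in union
  expect_equal(S["a", "c"], 0)         # disjoint
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))

  # both-empty convention: 1 on the diagonal, 0 off it
  expect_message(fe <- fingerprint_set(c("p", "q"), list(integer(), integer())),
                 "empty fingerprints")
  Se <- tanimoto_matrix(fe)
  expect_equal(Se["p", "q"], 0)
  expect_equal(diag(Se), c(p = 1, q = 1))

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:10, 1)
    bits <- lapply(seq_len(n), function(i) sample(0:15, sample(0:6, 1)))
    S <- tanimoto_matrix(fingerprint_set(paste0("f", seq_len(n)), bits))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) expect_equal(S[i, j], bf_tanimoto(bits[[i]], bits[[j]]))
    }
  }
})

test_that("patristic similarity matches path sums and normalization", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  S <- phylo_similarity(tr)
  # d(A,B)=3, d(A,C)=4.5, d(B,C)=5.5 -> normalized by 5.5
  expect_equal(S["A", "B"], 1 - 3 / 5.5)
  expect_equal(S["A", "C"], 1 - 4.5 / 5.5)
  expect_equal(S["B", "C"], 0)  # the pair realizing the maximum
  expect_equal(diag(S), c(A = 1, B = 1, C = 1))

  # degenerate cherry: the only distance is the maximum
  S2 <- phylo_similarity(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(S2["A", "B"], 0)

  # brute-force path-sum oracle on random trees with <= 10 leaves
  for (seed in 1:15) {
    set.seed(seed)
    tr <- ape::rtree(sample(3:10, 1))
    D <- bf_patristic(tr)
    S <- phylo_similarity(tr)
    expect_equal(unname(S[rownames(D), rownames(D)]), unname(1 - D / max(D)),
                 tolerance = 1e-12)
  }
  expect_error(phylo_similarity(ape::read.tree(text = "((A:1,A:2):1,B:1);")),
               "duplicate")
})

test_that("genome similarity is 1 - distance with symmetrization", {
  d <- matrix(c(0, 0.12, 0.12, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  S <- genome_similarity(d)
  expect_equal(S["a", "b"], 0.88)
  expect_equal(diag(S), c(a = 1, b = 1))
  expect_equal(genome_similarity(matrix(c(0, 1, 1, 0), 2, 2))[1, 2], 0)

  asym <- d; asym["a", "b"] <- 0.2
  expect_warning(Sa <- genome_similarity(asym), "symmetrized")
  expect_equal(Sa["a", "b"], 1 - 0.16)
  expect_error(genome_similarity(matrix(c(0, 1.5, 1.5, 0), 2, 2)), "\\[0, 1\\]")

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path, quote = FALSE)
  expect_equal(genome_similarity(path), S)
})

test_that("aggregation averages components, two levels deep", {
  ids <- c("a", "b", "c")
  A <- sim_matrix(ids, 0.8)
  B <- sim_matrix(ids, 0.6)
  M <- aggregate_similarity(list(A, B))
  expect_equal(M["a", "b"], 0.7)
  expect_equal(aggregate_similarity(list(A)), A)
  expect_error(aggregate_similarity(list()), "non-empty")

  # two-level nesting: mean(mean(A, B), C) on a 3x3 toy, by direct arithmetic
  C <- sim_matrix(ids, 0.2)
  nested <- microbe_similarity(gip_assoc = A, gip_metabolite = B, genomic = C)
  expect_equal(nested["a", "b"], ((0.8 + 0.6) / 2 + 0.2) / 2)

  # ids missing one component fall back to the mean of the available ones
  B_na <- B; B_na["c", ] <- NA; B_na[, "c"] <- NA
  suppressMessages(M2 <- aggregate_similarity(list(A, B_na)))
  expect_equal(M2["a", "b"], 0.7)
  expect_equal(M2["a", "c"], 0.8)
})

test_that("SMILES convert to fingerprints and failures are excluded", {
  skip_if_not_installed("ChemmineR")
  smi <- c(ethanol = "CCO", phenol = "c1ccccc1O", benzene = "c1ccccc1",
           broken = "not_a_smiles((")
  fps <- suppressWarnings(suppressMessages(smiles_fingerprints(smi)))
  expect_true("broken" %in% attr(fps, "failed"))
  expect_setequal(fps$ids, c("ethanol", "phenol", "benzene"))
  S <- tanimoto_matrix(fps)
  # shared aromatic ring: phenol closer to benzene than to ethanol
  expect_gt(S["phenol", "benzene"], S["phenol", "ethanol"])
  expect_equal(diag(S), c(ethanol = 1, phenol = 1, benzene = 1))
})
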
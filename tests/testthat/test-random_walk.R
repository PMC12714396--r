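test_that("the gate rho follows its case analysis", {
  # T = 0 (no metabolite edges): the walker must stay among same-type nodes
  reg <- node_registry(c("m1", "m2"), "c1", "d1")
  empty <- data.frame(i = integer(), j = integer(), w = numeric())
  g0 <- assemble_graph(reg, empty, empty, empty,
                       microbe_sim = sim_matrix(c("m1", "m2"), 0.9), alpha = 0.5)
  expect_equal(rho(g0, "m1"), 1)

  # metabolite edges but no same-type neighbor: always leave for metabolites
  g1 <- tiny_graph()
  expect_equal(rho(g1, "m1"), 0)

  # otherwise a steep sigmoid of the best same-type similarity
  g2 <- tiny_graph(microbe_sim = sim_matrix(c("m1", "m2"), 0.85), alpha = 0.5)
  expect_equal(rho(g2, "m1"), 0.5)  # S_v^max at the midpoint t
  g3 <- tiny_graph(microbe_sim = sim_matrix(c("m1", "m2"), 0.95), alpha = 0.5)
  expect_equal(rho(g3, "m1"), 1 / (1 + exp(-10)))

  expect_error(rho(g1, "c1"), "microbe and drug")
})

test_that("the sigmoid gate has its closed-form values and is monotone", {
  expect_identical(sigmoid_gate(0.85), 0.5)
  expect_equal(sigmoid_gate(0.95), 1 / (1 + exp(-10)))
  grid <- sigmoid_gate(seq(0, 1, length.out = 100))
  expect_true(all(diff(grid) > 0))
})

test_that("metabolite-node transition law weighs neighbors by the M factor", {
  g <- tiny_graph()
  # c1 has neighbors m1 (sm) and c2 (mm); biased M with M[sm, sm] = 2
  M <- transition_init()
  M["sm", "sm"] <- 2
  p <- metabolite_step_probs(g, M, u = "m1", v = "c2")
  # from u = m1 the incoming type is sm; neighbors m1, m2 (sm, factor 2),
  # c1, c3 (mm, factor 1), d1 (dm, factor 1)
  expect_equal(p$prob[p$id %in% c("m1", "m2")], c(2 / 7, 2 / 7))
  expect_equal(p$prob[p$id %in% c("c1", "c3", "d1")], rep(1 / 7, 3))
  expect_equal(sum(p$prob), 1)

  # a walk start (u = NULL) uses no M factor
  p0 <- metabolite_step_probs(g, M, u = NULL, v = "c2")
  expect_equal(p0$prob, rep(1 / 5, 5))

  # single neighbor gets probability 1; isolation truncates
  p1 <- metabolite_step_probs(g, M, u = NULL, v = "c1")
  expect_equal(nrow(p1), 2)  # m1 via sm, c2 via mm
  reg <- node_registry("m1", c("c1", "c2"), character())
  empty <- data.frame(i = integer(), j = integer(), w = numeric())
  g_iso <- assemble_graph(reg, edge_table("m1", "c1", "sm", reg), empty, empty)
  expect_equal(nrow(metabolite_step_probs(g_iso, M, v = "c2")), 0)
  expect_equal(metabolite_step_probs(g_iso, M, v = "c1")$prob, 1)
  expect_error(metabolite_step_probs(g_iso, M, u = "m1", v = "c2"), "adjacent")
})

test_that("typed transition law splits mass rho / 1 - rho across the blocks", {
  # m1: ss neighbor m2 (0.9), ss neighbor m3 (0.6), metabolites c1, c2.
  # With midpoint t = 0.9 the gate is exactly 0.5, so the same-type block
  # carries (0.3, 0.2) and each metabolite 0.25.
  reg <- node_registry(c("m1", "m2", "m3"), c("c1", "c2"), character())
  S <- sim_matrix(reg$microbes, 0)
  S["m1", "m2"] <- S["m2", "m1"] <- 0.9
  S["m1", "m3"] <- S["m3", "m1"] <- 0.6
  empty <- data.frame(i = integer(), j = integer(), w = numeric())
  sm <- edge_table(c("m1", "m1"), c("c1", "c2"), "sm", reg)
  g <- assemble_graph(reg, sm, empty, empty, microbe_sim = S, alpha = 0.5)
  cfg <- walk_config(t = 0.9)
  p <- typed_step_probs(g, "m1", cfg)
  expect_equal(p$prob[p$id == "m2"], 0.3)
  expect_equal(p$prob[p$id == "m3"], 0.2)
  expect_equal(p$prob[p$id %in% c("c1", "c2")], c(0.25, 0.25))

  # T = 0: all mass on same-type neighbors, proportional to similarity
  g0 <- assemble_graph(reg, empty, empty, empty, microbe_sim = S, alpha = 0.5)
  p0 <- typed_step_probs(g0, "m1", cfg)
  expect_equal(p0$prob, c(0.9, 0.6) / 1.5)

  # no same-type neighbors, T != 0: uniform over metabolite neighbors
  g1 <- assemble_graph(reg, sm, empty, empty, microbe_sim = S, alpha = 0.95)
  p1 <- typed_step_probs(g1, "m1", cfg)
  expect_equal(p1$prob, c(0.5, 0.5))
})

test_that("every emitted distribution is a distribution", {
  for (seed in 1:25) {
    g <- random_small_graph(seed)
    reg <- g$registry
    R <- matrix(runif(25), 5, 5)
    M <- transition_init() + (R + t(R)) / 2
    for (v in reg$metabolites) {
      nb <- graph_neighbors(g, v)
      for (u in c(list(NULL), as.list(nb$id))) {
        p <- metabolite_step_probs(g, M, u = u, v = v)
        if (nrow(p) > 0) {
          expect_equal(sum(p$prob), 1, tolerance = 1e-9)
          expect_true(all(p$prob >= 0))
        }
      }
    }
    for (v in c(reg$microbes, reg$drugs)) {
      p <- typed_step_probs(g, v)
      if (nrow(p) > 0) {
        expect_equal(sum(p$prob), 1, tolerance = 1e-9)
        expect_true(all(p$prob >= 0))
      }
    }
  }
})

test_that("corpora are valid, budgeted, reproducible paths", {
  d <- small_synth(seed = 21)
  g <- assemble_graph(d$registry, d$sm_edges, d$mm_edges, d$dm_edges,
                      d$microbe_functional, d$drug_functional, alpha = 0.6)
  cfg <- walk_config(walks_per_node = 10, walk_length = 10, seed = 17)
  corpus <- generate_corpus(g, NULL, cfg)
  N <- length(corpus$node_ids)
  expect_lte(length(corpus$sentences), N * 10)
  expect_true(all(lengths(corpus$sentences) <= 10))
  expect_true(all(lengths(corpus$sentences) >= 1))

  # every consecutive pair is a graph edge
  adj <- mmdwalk:::build_adjacency(g)
  for (s in corpus$sentences[seq(1, length(corpus$sentences), by = 7)]) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      expect_true(s[i + 1] %in% adj[[s[i]]]$nbr)
    }
  }

  # bit-identical under the same seed
  corpus2 <- generate_corpus(g, NULL, cfg)
  expect_identical(corpus2$sentences, corpus$sentences)
  corpus3 <- generate_corpus(g, NULL, walk_config(walks_per_node = 10, seed = 18))
  expect_false(identical(corpus3$sentences, corpus$sentences))

  # corpus file round-trip
  path <- withr::local_tempfile(fileext = ".txt")
  save_corpus(corpus, path)
  back <- load_corpus(path)
  expect_identical(back$sentences, corpus$sentences)
  expect_identical(back$node_ids, corpus$node_ids)
})
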
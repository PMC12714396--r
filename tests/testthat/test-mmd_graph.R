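test_that("registry enforces unique, trimmed, typed ids", {
  reg <- node_registry(c(" m1", "m2 "), "c1", "d1")
  expect_equal(reg$microbes, c("m1", "m2"))
  expect_equal(node_type(reg, c("m2", "c1", "d1", "nope")),
               c("microbe", "metabolite", "drug", NA))
  expect_error(node_registry(c("a", "a"), "c", "d"), "duplicate")
  expect_error(node_registry("a", "a", "d"), "shared across types")
})

test_that("edge tables deduplicate, drop unknown ids and report them", {
  reg <- node_registry(c("m1", "m2"), c("c1", "c3"), character())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "m1\tc1", "m1\tc1", "m2\tc3", "mX\tc1"), path)
  expect_message(e <- load_edge_table(path, "sm", reg), "dropped")
  expect_equal(nrow(e), 2)
  expect_equal(e$w, c(1, 1))
  expect_equal(attr(e, "dropped")$source, "mX")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source\ttarget", empty)
  expect_warning(e0 <- load_edge_table(empty, "mm", reg), "empty")
  expect_equal(nrow(e0), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "m1\tc1", "\tc3"), bad)
  expect_error(load_edge_table(bad, "sm", reg), "line 3")
})

test_that("an MDAD-scale association table loads with one 1 per entry", {
  set.seed(42)
  microbes <- sprintf("microbe%03d", 1:173)
  drugs <- sprintf("drug%04d", 1:1373)
  reg <- node_registry(microbes, character(), drugs)
  all_pairs <- expand.grid(m = microbes, d = drugs, stringsAsFactors = FALSE)
  pairs <- all_pairs[sample.int(nrow(all_pairs), 2470), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(microbe = pairs$m, drug = pairs$d), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  I <- load_association_table(path, reg)
  expect_equal(dim(I), c(173, 1373))
  expect_equal(sum(I), 2470)
  expect_true(all(I %in% 0:1))
})

test_that("same-type edges require similarity strictly above alpha", {
  reg <- node_registry(c("m1", "m2", "m3"), "c1", character())
  S <- sim_matrix(reg$microbes, 0)
  S["m1", "m2"] <- S["m2", "m1"] <- 0.7
  S["m1", "m3"] <- S["m3", "m1"] <- 0.6
  S["m2", "m3"] <- S["m3", "m2"] <- 0.64
  empty <- data.frame(i = integer(), j = integer(), w = numeric())
  g <- assemble_graph(reg, empty, empty, empty, microbe_sim = S, alpha = 0.65)
  expect_equal(nrow(g$edges$ss), 1)
  expect_equal(g$edges$ss$w, 0.7)

  # a value exactly at alpha does not create an edge
  g2 <- assemble_graph(reg, empty, empty, empty, microbe_sim = S, alpha = 0.7)
  expect_equal(nrow(g2$edges$ss), 0)

  # alpha = 1 leaves metabolite-only structure, still a valid graph
  g3 <- tiny_graph(sim_matrix(c("m1", "m2"), 0.99),
                   sim_matrix(c("d1", "d2"), 0.99), alpha = 1)
  expect_equal(nrow(g3$edges$ss), 0)
  expect_equal(nrow(g3$edges$dd), 0)
  expect_gt(nrow(g3$edges$sm), 0)

  asym <- S; asym["m1", "m2"] <- 0.2
  expect_error(assemble_graph(reg, empty, empty, empty, microbe_sim = asym),
               "asymmetric")
  expect_error(assemble_graph(reg, empty, empty, empty, alpha = 1.2), "alpha")
})

test_that("neighbors are complete, ordered, filterable and symmetric", {
  g <- tiny_graph(sim_matrix(c("m1", "m2"), 0.9), alpha = 0.65)
  nb <- graph_neighbors(g, "c2")  # m1, m2 via sm; c1, c3 via mm; d1 via dm
  expect_equal(nb$id, c("m1", "m2", "c1", "c3", "d1"))
  expect_equal(nb$edge_type, c("sm", "sm", "mm", "mm", "dm"))

  mets <- graph_neighbors(g, "m1", type_filter = "metabolite")
  expect_equal(mets$id, c("c1", "c2"))
  expect_equal(graph_neighbors(g, "m1", type_filter = "microbe")$id, "m2")

  # undirected edges visible from both endpoints with the same type
  expect_equal(edge_type(g, "m1", "c1"), "sm")
  expect_equal(edge_type(g, "c1", "m1"), "sm")
  expect_true(is.na(edge_type(g, "m1", "d1")))
  expect_error(graph_neighbors(g, "zzz"), "unknown node")

  # isolated node: empty neighbor list, no error
  reg <- node_registry("m1", c("c1", "c2"), character())
  g_iso <- assemble_graph(reg, edge_table("m1", "c1", "sm", reg),
                          data.frame(i = integer(), j = integer(), w = numeric()),
                          data.frame(i = integer(), j = integer(), w = numeric()))
  expect_equal(nrow(graph_neighbors(g_iso, "c2")), 0)
})

test_that("no graph ever stores a microbe-drug edge", {
  for (seed in 1:20) {
    g <- random_small_graph(seed)
    el <- mmdwalk:::graph_edge_list(g)
    types <- mmdwalk:::registry_types(g$registry)
    expect_false(any((types[el$src] == 1 & types[el$dst] == 3) |
                     (types[el$src] == 3 & types[el$dst] == 1)))
  }
})

test_that("graph serialization round-trips bit-equal", {
  g <- random_small_graph(99)
  dir <- withr::local_tempdir()
  save_graph(g, dir)
  g2 <- load_graph(dir)
  expect_identical(g2$registry, g$registry)
  for (kind in c("ss", "sm", "mm", "dm", "dd")) {
    expect_identical(g2$edges[[kind]]$i, g$edges[[kind]]$i)
    expect_identical(g2$edges[[kind]]$j, g$edges[[kind]]$j)
    expect_identical(g2$edges[[kind]]$w, g$edges[[kind]]$w)
  }
  expect_identical(g2$alpha, g$alpha)
})
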
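test_that("ego-networks exclude the ego and keep induced edges", {
  path <- graph_from_pairs("a", "b", "b", "c")
  ego_b <- ego_network(path, "b")
  expect_setequal(igraph::V(ego_b)$name, c("a", "c"))
  expect_equal(igraph::ecount(ego_b), 0L)

  tri <- graph_from_pairs("a", "b", "b", "c", "c", "a")
  ego_a <- ego_network(tri, "a")
  expect_setequal(igraph::V(ego_a)$name, c("b", "c"))
  expect_equal(igraph::ecount(ego_a), 1L)

  # the two-role bridge of the toy graph: ego-net has two components
  comp <- igraph::components(ego_network(fig1_toy(), "C"))
  expect_equal(comp$no, 2L)
  expect_setequal(split(names(comp$membership), comp$membership),
                  list(c("A", "B"), c("D", "E", "F")))

  expect_error(ego_network(tri, "zz"), "not in graph")
})

test_that("directed ego-networks use the union of in- and out-neighbours", {
  g <- graph_from_pairs("u", "v", "w", "v", "u", "w", directed = TRUE)
  ego_v <- ego_network(g, "v")
  expect_setequal(igraph::V(ego_v)$name, c("u", "w"))
  expect_false(igraph::is_directed(ego_v))
  expect_equal(igraph::ecount(ego_v), 1L)
})

test_that("local clustering partitions the ego-network deterministically", {
  two_edges <- graph_from_pairs("a", "b", "c", "d")
  cl <- local_clusters(two_edges)
  expect_length(cl, 2L)
  expect_equal(lengths(cl), c(2L, 2L))
  # deterministic order: sorted by smallest member
  expect_equal(vapply(cl, min, character(1L)), c("a", "c"))

  expect_identical(local_clusters(igraph::make_empty_graph(0)), list())

  # louvain and label propagation agree with components on disconnected input
  two_cliques <- graph_from_pairs("x", "y", "u", "v", "v", "w", "u", "w")
  ref <- local_clusters(two_cliques, "connected_components")
  expect_equal(local_clusters(two_cliques, "louvain", seed = 5), ref)
  expect_equal(local_clusters(two_cliques, "label_propagation", seed = 5), ref)

  expect_error(local_clusters(two_edges, "kmeans"), "arg")

  # custom partitioners are accepted, bad covers rejected
  fn <- function(g) list(igraph::V(g)$name)
  expect_length(local_clusters(two_edges, fn), 1L)
  bad <- function(g) list(igraph::V(g)$name[1L])
  expect_error(local_clusters(two_edges, bad), "partition")
})

test_that("persona splitting counts roles per node", {
  pm <- split_personas(bowtie_graph())
  np <- persona_counts(pm)
  expect_equal(np[["x"]], 2L)
  expect_equal(unname(np[names(np) != "x"]), rep(1L, 4L))
  expect_equal(length(pm$p2c), 6L)
  # persona clusters partition each ego-network
  expect_setequal(unlist(pm$p2c[pm$v2p[["x"]]]), c("a", "b", "c", "d"))

  # complete graphs never split (every ego-net is connected)
  k4 <- canonicalize_graph(igraph::make_full_graph(4))
  expect_true(all(persona_counts(split_personas(k4)) == 1L))

  # isolated nodes keep one persona with an empty cluster
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "lone"
  pm_iso <- split_personas(canonicalize_graph(iso))
  expect_equal(persona_counts(pm_iso)[["lone"]], 1L)
  expect_length(pm_iso$p2c[[pm_iso$v2p[["lone"]]]], 0L)

  # persona ids are unique and deterministically derived
  expect_false(anyDuplicated(names(pm$p2c)) > 0)
  expect_identical(pm$v2p[["x"]], c("x#1", "x#2"))
})

test_that("persona graph inherits original edges and weights persona edges", {
  g <- bowtie_graph()
  pm <- split_personas(g)
  pg <- build_persona_graph(g, pm, lambda = 0.5)
  kind <- igraph::E(pg$graph)$kind
  w <- igraph::E(pg$graph)$weight

  # undirected input: every original edge appears as two directed edges
  expect_equal(sum(kind == "original"), 2L * igraph::ecount(g))
  # both personas of x have original out-strength 2 -> persona edges 0.5 * 2
  expect_equal(sum(kind == "persona"), 2L)
  expect_equal(unname(w[kind == "persona"]), c(1, 1))
  expect_equal(unname(pg$k_out_original[pm$v2p[["x"]]]), c(2, 2))

  # unsplittable graph: persona graph isomorphic to original, no persona edges
  tri <- graph_from_pairs("a", "b", "b", "c", "c", "a")
  pg_tri <- build_persona_graph(tri, split_personas(tri), lambda = 0.5)
  expect_equal(igraph::ecount(pg_tri$graph), 6L)
  expect_true(all(igraph::E(pg_tri$graph)$kind == "original"))

  # lambda = 0 needs an explicit override and yields zero-weight edges
  expect_error(build_persona_graph(g, pm, lambda = 0), "allow_zero_lambda")
  pg0 <- build_persona_graph(g, pm, lambda = 0, allow_zero_lambda = TRUE)
  expect_equal(unname(igraph::E(pg0$graph)$weight[
    igraph::E(pg0$graph)$kind == "persona"]), c(0, 0))
  expect_error(build_persona_graph(g, pm, lambda = -1), "non-negative")

  # corrupted mapping surfaces as a consistency error
  broken <- pm
  broken$p2c[["x#1"]] <- "d"  # no longer covers neighbour "a"
  expect_error(build_persona_graph(g, broken, 0.5), "consistency")
})

test_that("directed edges land on the personas owning the opposite endpoint", {
  g <- graph_from_pairs("a", "b", "b", "c", "c", "a", "b", "d",
                        directed = TRUE)
  pm <- split_personas(g)
  pg <- build_persona_graph(g, pm, lambda = 0.5)
  kind <- igraph::E(pg$graph)$kind
  expect_equal(sum(kind == "original"), igraph::ecount(g))
  # b has neighbours {a, c, d}; a-c are linked through the a->b->c triangle
  np <- persona_counts(pm)
  expect_equal(np[["b"]], 2L)
  # every persona's original out-strength matches the recorded k_out
  for (p in names(pg$k_out_original)) {
    eids <- igraph::incident(pg$graph, p, mode = "out")
    ke <- as.integer(eids)
    expect_equal(
      sum(igraph::E(pg$graph)$weight[ke][igraph::E(pg$graph)$kind[ke] ==
                                           "original"]),
      unname(pg$k_out_original[p])
    )
  }
})

test_that("escape probability follows 1 / (1 + (n_p - 1) lambda)", {
  # unsplit node: probability 1
  tri <- graph_from_pairs("a", "b", "b", "c", "c", "a")
  pg_tri <- build_persona_graph(tri, split_personas(tri), lambda = 0.5)
  expect_equal(escape_probability(pg_tri, "a#1"), 1.0)

  # two K5 cliques sharing the hub: k_o = 4, n_p = 2, lambda = 0.5 -> 2/3
  g <- star_of_cliques(c(5, 5))
  pg <- build_persona_graph(g, split_personas(g), lambda = 0.5)
  hubs <- pg$v2p[["h"]]
  expect_length(hubs, 2L)
  expect_equal(escape_probability(pg, hubs[1L]), 2 / 3)

  # personas with different degrees still share the escape probability
  g2 <- star_of_cliques(c(5, 3))
  pg2 <- build_persona_graph(g2, split_personas(g2), lambda = 0.7)
  hubs2 <- pg2$v2p[["h"]]
  k <- unname(pg2$k_out_original[hubs2])
  expect_equal(k, c(4, 2))  # different k_i^o
  p1 <- escape_probability(pg2, hubs2[1L])
  p2 <- escape_probability(pg2, hubs2[2L])
  expect_equal(p1, p2)
  expect_equal(p1, 1 / (1 + (2 - 1) * 0.7))

  # degenerate persona with zero out-weight
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "lone"
  iso <- canonicalize_graph(iso)
  pg_iso <- build_persona_graph(iso, split_personas(iso), lambda = 0.5)
  expect_error(escape_probability(pg_iso, "lone#1"), "undefined")
  expect_error(escape_probability(pg, "nope"), "unknown persona")
})

test_that("persona-graph structure laws hold on random planted graphs", {
  set.seed(202)
  for (rep in 1:12) {
    n_cl <- sample(2:6, 1)
    res <- planted_overlap_graph(
      n_cliques = n_cl, clique_size = sample(4:7, 1),
      n_bridges = sample.int(min(3, floor(n_cl^2 / 4)), 1),
      noise_p = stats::runif(1, 0, 0.1), seed = rep * 13L
    )
    g <- res$graph
    pm <- split_personas(g)
    pg <- build_persona_graph(g, pm, lambda = 0.5)
    kind <- igraph::E(pg$graph)$kind
    np <- persona_counts(pm)
    deg <- igraph::degree(g)[names(np)]

    expect_equal(sum(kind == "original"), 2L * igraph::ecount(g))
    expect_equal(sum(kind == "persona"), sum(np * (np - 1L)))
    expect_equal(sum(np), igraph::vcount(pg$graph))
    expect_true(all(np[deg >= 1] <= deg[deg >= 1]))
    expect_true(sum(kind == "persona") <= igraph::ecount(g)^1.5)
  }
})

test_that("persona graph exports round-trip as text", {
  g <- bowtie_graph()
  pg <- build_persona_graph(g, split_personas(g), lambda = 0.5)
  prefix <- tempfile()
  paths <- write_persona_graph(pg, prefix)
  expect_true(all(file.exists(paths)))
  el <- read.table(paths[1L], stringsAsFactors = FALSE, comment.char = "")
  expect_equal(nrow(el), igraph::ecount(pg$graph))
  expect_setequal(unique(el$V4), c("original", "persona"))
  v2p <- read.table(paths[2L], sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "")
  expect_equal(nrow(v2p), length(pg$p2n))
})
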
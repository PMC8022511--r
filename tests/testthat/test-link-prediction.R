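test_that("edge splitting preserves connectivity and hits the target size", {
  k <- karate_club()
  split <- split_edges(k, test_fraction = 0.2, seed = 4)
  expect_equal(nrow(split$test_edges), 16L)  # round(0.2 * 78)
  expect_equal(igraph::ecount(split$train_graph), 78L - 16L)
  expect_true(igraph::is_connected(split$train_graph))

  ring <- canonicalize_graph(igraph::make_ring(10))
  sp <- split_edges(ring, 0.1, seed = 1)
  expect_equal(nrow(sp$test_edges), 1L)
  expect_true(igraph::is_connected(sp$train_graph))

  tree <- canonicalize_graph(igraph::make_tree(15, children = 2,
                                               mode = "undirected"))
  expect_error(split_edges(tree, 0.5, seed = 1), "infeasible")

  expect_error(split_edges(k, 0), "between 0 and 1")
  two_comp <- graph_from_pairs("a", "b", "c", "d")
  expect_error(split_edges(two_comp, 0.5), "connected")
})

test_that("held-out and train edges partition the edge set", {
  set.seed(99)
  for (rep in 1:5) {
    res <- planted_overlap_graph(4, 5, n_bridges = 3, noise_p = 0.05,
                                 seed = rep)
    g <- largest_connected_component(res$graph)
    split <- split_edges(g, 0.3, seed = rep * 7L)
    expect_true(igraph::is_connected(split$train_graph, mode = "weak"))
    ekey <- function(el) paste(pmin(el[, 1], el[, 2]),
                               pmax(el[, 1], el[, 2]))
    all_e <- ekey(igraph::as_edgelist(g, names = TRUE))
    train_e <- ekey(igraph::as_edgelist(split$train_graph, names = TRUE))
    test_e <- ekey(split$test_edges)
    expect_length(intersect(train_e, test_e), 0L)
    expect_setequal(c(train_e, test_e), all_e)
  }
})

test_that("negative sampling draws true non-edges", {
  k5 <- canonicalize_graph(igraph::make_full_graph(5))
  expect_error(sample_negative_edges(k5, 1), "non-edges")

  empty3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty3)$name <- c("a", "b", "c")
  negs <- sample_negative_edges(canonicalize_graph(empty3), 3, seed = 2)
  expect_setequal(paste(negs[, 1L], negs[, 2L]), c("a b", "a c", "b c"))

  path <- graph_from_pairs("a", "b", "b", "c")
  only <- sample_negative_edges(path, 1, seed = 5)
  expect_equal(sort(as.vector(only)), c("a", "c"))

  # sampled negatives never collide with edges or themselves
  res <- planted_overlap_graph(3, 5, n_bridges = 2, seed = 8)
  g <- res$graph
  negs2 <- sample_negative_edges(g, 40, seed = 11)
  expect_equal(nrow(unique(as.data.frame(negs2))), 40L)
  expect_true(all(negs2[, 1L] != negs2[, 2L]))
  eid <- apply(negs2, 1L, function(p) {
    igraph::get_edge_ids(g, p, directed = FALSE)
  })
  expect_true(all(eid == 0))
})

test_that("directed negatives may reverse an existing edge", {
  g <- graph_from_pairs("a", "b", "b", "c", "c", "a", directed = TRUE)
  negs <- sample_negative_edges(g, 3, seed = 1)
  keys <- paste(negs[, 1L], negs[, 2L])
  expect_setequal(keys, c("b a", "c b", "a c"))
})

test_that("pair scores aggregate persona similarities", {
  emb1 <- embedding_matrix(c("u#1", "v#1"), rbind(c(1, 0), c(1, 0)),
                           matrix(0, 2, 2))
  v2p1 <- list(u = "u#1", v = "v#1")
  expect_equal(score_pair(emb1, v2p1, "u", "v"), 1.0)

  emb <- embedding_matrix(
    c("u#1", "u#2", "v#1", "v#2"),
    rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 3)),
    matrix(0, 4, 2)
  )
  v2p <- list(u = c("u#1", "u#2"), v = c("v#1", "v#2"))
  expect_equal(score_pair(emb, v2p, "u", "v", "max"), 3.0)
  expect_equal(score_pair(emb, v2p, "u", "v", "min"), 0.0)
  expect_equal(score_pair(emb, v2p, "u", "v", "mean"), 5 / 4)
  # cosine ignores vector magnitude
  expect_equal(score_pair(emb, v2p, "u", "v", "max", "cosine"), 1.0)
  # max aggregation is invariant to persona order
  v2p_rev <- list(u = c("u#2", "u#1"), v = c("v#2", "v#1"))
  expect_equal(score_pair(emb, v2p_rev, "u", "v", "max"),
               score_pair(emb, v2p, "u", "v", "max"))
  expect_error(score_pair(emb, v2p, "w", "v"), "unknown node")
})

test_that("roc_auc equals the brute-force pairwise probability", {
  expect_equal(roc_auc(c(2, 3), c(0, 1)), 1.0)
  expect_equal(roc_auc(1, 1), 0.5)
  expect_equal(roc_auc(c(3, 1), c(2, 0)), 0.75)
  expect_error(roc_auc(numeric(0), 1), "non-empty")

  set.seed(42)
  for (rep in 1:10) {
    pos <- sample(0:10, sample(3:200, 1), replace = TRUE)
    neg <- sample(0:10, sample(3:200, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg), auc_brute_force(pos, neg))
  }

  # random scores hover around chance
  set.seed(7)
  expect_lt(abs(roc_auc(stats::runif(1000), stats::runif(1000)) - 0.5), 0.1)
})

test_that("the benchmark pipeline is deterministic and self-consistent", {
  res <- planted_overlap_graph(4, 6, n_bridges = 3, noise_p = 0.02, seed = 2)
  g <- largest_connected_component(res$graph)
  cfg <- train_config(d = 16)
  b1 <- run_benchmark(g, cfg, seed = 10)
  b2 <- run_benchmark(g, cfg, seed = 10)
  expect_identical(b1$auc, b2$auc)
  expect_identical(b1$auc_base, b2$auc_base)
  expect_equal(b1$n_test, round(0.5 * igraph::ecount(g)))
  expect_gte(b1$auc, 0)
  expect_lte(b1$auc, 1)
  expect_equal(b1$n_nodes, igraph::vcount(g))
})
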
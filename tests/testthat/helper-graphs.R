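# Small graph builders and independent oracles shared across the suite.

graph_from_pairs <- function(..., directed = FALSE) {
  m <- matrix(c(...), ncol = 2L, byrow = TRUE)
  canonicalize_graph(igraph::graph_from_edgelist(m, directed = directed))
}

# two triangles sharing the node "x"
bowtie_graph <- function() {
  graph_from_pairs(
    "x", "a", "x", "b", "a", "b",
    "x", "c", "x", "d", "c", "d"
  )
}

# n_p cliques of the given sizes all sharing one hub node "h"
star_of_cliques <- function(sizes) {
  edges <- character(0L)
  for (k in seq_along(sizes)) {
    mem <- c("h", sprintf("q%d_%d", k, seq_len(sizes[k] - 1L)))
    pr <- utils::combn(mem, 2L)
    edges <- c(edges, as.vector(pr))
  }
  graph_from_pairs(edges)
}

write_tmp_edgelist <- function(lines) {
  f <- tempfile(fileext = ".edgelist")
  writeLines(lines, f)
  f
}

# brute-force pairwise AUC oracle, ties counted one half
auc_brute_force <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# reference SGNS loss for one (center, targets, labels) update, used as the
# finite-difference oracle for the analytic gradient
sgns_loss_ref <- function(center, targets, labels) {
  s <- as.numeric(targets %*% center)
  f <- 1 / (1 + exp(-s))
  -sum(ifelse(labels > 0, log(f), log(1 - f)))
}

# count persona-edge vs original-edge transitions out of given personas
# along a walk corpus
count_hub_transitions <- function(corpus, pg, hub_personas) {
  orig <- 0L; pers <- 0L
  for (wk in corpus$walks) {
    if (length(wk) < 2L) next
    from <- wk[-length(wk)]
    to <- wk[-1L]
    sel <- from %in% hub_personas
    if (!any(sel)) next
    same_parent <- pg$p2n[from[sel]] == pg$p2n[to[sel]]
    pers <- pers + sum(same_parent)
    orig <- orig + sum(!same_parent)
  }
  c(original = orig, persona = pers)
}
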
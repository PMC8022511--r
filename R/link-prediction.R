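#' Connectivity-preserving train/test edge split
#'
#' Splits the edge set into a training graph and a held-out positive test
#' set by rejection sampling: candidate edges are drawn uniformly without
#' replacement, and a candidate whose removal would disconnect the current
#' training graph (weakly, for directed graphs) is rejected.  The training
#' graph therefore always remains connected as a single component, which is
#' required for random-walk training.  The test-set size is
#' `round(test_fraction * |E|)`.
#'
#' An edge that is a bridge of the current training graph stays a bridge
#' under further removals, so rejected candidates are never revisited; if
#' the candidates are exhausted (or `100 * |E|` consecutive rejections
#' occur) before the target is reached the split is infeasible and an error
#' reports how many removable edges were found.
#'
#' @param g A connected canonical graph.
#' @param test_fraction Fraction of edges to hold out, in (0, 1).
#' @param seed Integer seed.
#' @return A `link_split`: list with `train_graph`, `test_edges` (2-column
#'   character matrix), `negative_edges` (`NULL` until
#'   [sample_negative_edges()] fills it), `test_fraction`, `seed`.
#' @export
split_edges <- function(g, test_fraction = 0.5, seed = 1L) {
  stopifnot(igraph::is_igraph(g))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (!igraph::is_connected(g, mode = "weak")) {
    stop("graph must be connected before splitting edges", call. = FALSE)
  }
  m <- igraph::ecount(g)
  target <- round(test_fraction * m)
  if (target < 1L) {
    stop("test fraction too small: no edges selected", call. = FALSE)
  }
  train <- g
  removed <- matrix(character(0L), ncol = 2L)
  candidates <- with_seed(seed, sample.int(m))
  rejections <- 0L
  max_rejections <- 100L * m
  for (eid in candidates) {
    if (nrow(removed) >= target) break
    ends <- igraph::ends(g, eid, names = TRUE)
    te <- igraph::get_edge_ids(train, as.vector(t(ends)))
    if (te == 0) next  # already removed (cannot happen with unique draws)
    cand <- igraph::delete_edges(train, te)
    if (igraph::is_connected(cand, mode = "weak")) {
      train <- cand
      removed <- rbind(removed, ends)
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
      if (rejections >= max_rejections) break
    }
  }
  if (nrow(removed) < target) {
    stop(sprintf(paste0(
      "connectivity-preserving split infeasible: wanted %d test edges ",
      "but only %d edges are removable"), target, nrow(removed)),
      call. = FALSE)
  }
  structure(
    list(train_graph = train, test_edges = unname(removed),
         negative_edges = NULL, test_fraction = test_fraction,
         seed = as.integer(seed)),
    class = "link_split"
  )
}

#' @export
print.link_split <- function(x, ...) {
  cat(sprintf(
    "link_split: %d train edges, %d test edges, %s negatives (fraction %g)\n",
    igraph::ecount(x$train_graph), nrow(x$test_edges),
    if (is.null(x$negative_edges)) "no" else nrow(x$negative_edges),
    x$test_fraction))
  invisible(x)
}

#' Sample non-existent edges
#'
#' Draws `n` distinct node pairs uniformly from the non-edges of the full
#' graph (ordered pairs for directed graphs, unordered otherwise; never
#' self-pairs).  For directed graphs the reverse of an existing edge is a
#' valid negative when that direction is absent.  Negatives are judged
#' against the complete graph, not the training graph, so a held-out test
#' edge can never be drawn as a negative.
#'
#' @param g The full canonical graph.
#' @param n Number of negatives; must not exceed the number of non-edges.
#' @param seed Integer seed.
#' @return A 2-column character matrix of node pairs.
#' @export
sample_negative_edges <- function(g, n, seed = 1L) {
  stopifnot(igraph::is_igraph(g), n >= 1L)
  ids <- igraph::V(g)$name
  nv <- length(ids)
  directed <- igraph::is_directed(g)
  n_pairs <- if (directed) nv * (nv - 1) else nv * (nv - 1) / 2
  n_available <- n_pairs - igraph::ecount(g)
  if (n > n_available) {
    stop(sprintf("requested %d negative edges but only %g non-edges exist",
                 n, n_available), call. = FALSE)
  }
  key <- function(a, b) paste(a, b, sep = "\r")
  el <- igraph::as_edgelist(g, names = TRUE)
  existing <- if (directed) key(el[, 1L], el[, 2L]) else
    c(key(el[, 1L], el[, 2L]), key(el[, 2L], el[, 1L]))
  with_seed(seed, {
    if (n_pairs <= 2e5) {
      # small graphs: enumerate all non-edges and sample exactly
      all_pairs <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$a != all_pairs$b, ]
      if (!directed) all_pairs <- all_pairs[all_pairs$a < all_pairs$b, ]
      free <- !(key(all_pairs$a, all_pairs$b) %in% existing)
      pool <- all_pairs[free, , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
      unname(as.matrix(pick))
    } else {
      # large sparse graphs: rejection sampling
      chosen <- character(0L)
      out <- matrix(character(0L), ncol = 2L)
      while (nrow(out) < n) {
        a <- ids[sample.int(nv, 1L)]
        b <- ids[sample.int(nv, 1L)]
        if (a == b) next
        if (!directed && a > b) { tmp <- a; a <- b; b <- tmp }
        k <- key(a, b)
        if (k %in% existing || k %in% chosen) next
        chosen <- c(chosen, k)
        out <- rbind(out, c(a, b))
      }
      out
    }
  })
}

#' Similarity score of a node pair from persona embeddings
#'
#' Nodes with several personas have several candidate similarities; the
#' pair score aggregates the similarity over all persona pairs of the two
#' nodes.  The default (`max` aggregation of dot products) scores a pair by
#' its most compatible persona pair, which is the recommended combination
#' for negative-sampling models; cosine similarity works better with
#' hierarchical-softmax models.
#'
#' @param emb An `embedding_matrix` over persona ids (or plain node ids).
#' @param v2p Node -> persona-id list; `NULL` treats ids in `emb` as nodes.
#' @param u,v Node ids.
#' @param aggregation `"max"`, `"mean"` or `"min"`.
#' @param similarity `"dot"` or `"cosine"`.
#' @return A scalar score.
#' @export
score_pair <- function(emb, v2p, u, v, aggregation = c("max", "mean", "min"),
                       similarity = c("dot", "cosine")) {
  aggregation <- match.arg(aggregation)
  similarity <- match.arg(similarity)
  stopifnot(inherits(emb, "embedding_matrix"))
  pu <- if (is.null(v2p)) u else v2p[[u]]
  pv <- if (is.null(v2p)) v else v2p[[v]]
  if (is.null(pu) || is.null(pv) || length(pu) == 0L || length(pv) == 0L) {
    stop("unknown node: ", if (is.null(pu) || length(pu) == 0L) u else v,
         call. = FALSE)
  }
  iu <- match(pu, emb$ids); iv <- match(pv, emb$ids)
  if (anyNA(iu) || anyNA(iv)) {
    stop("persona missing from embedding", call. = FALSE)
  }
  a <- emb$input[iu, , drop = FALSE]
  b <- emb$input[iv, , drop = FALSE]
  if (similarity == "cosine") {
    a <- a / pmax(sqrt(rowSums(a^2)), .Machine$double.eps)
    b <- b / pmax(sqrt(rowSums(b^2)), .Machine$double.eps)
  }
  s <- a %*% t(b)
  switch(aggregation, max = max(s), mean = mean(s), min = min(s))
}

#' ROC-AUC of positive versus negative scores
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, ties counted one half (the Mann-Whitney statistic
#' normalized by the number of pairs), computed from midranks.
#'
#' @param pos_scores,neg_scores Non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  stopifnot(is.numeric(pos_scores), is.numeric(neg_scores),
            !anyNA(pos_scores), !anyNA(neg_scores))
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Run the link-prediction benchmark on one graph
#'
#' The full evaluation pipeline: hold out a fraction of edges with
#' [split_edges()], sample an equally sized negative set against the full
#' graph, fit [persona2vec()] on the training graph, score the held-out and
#' negative pairs, and report ROC-AUC.  The base (single-vector) embedding
#' trained in the first stage is scored on the same pairs as a built-in
#' baseline, so the persona gain is read off directly.
#'
#' @param g A connected canonical graph.
#' @param config A [train_config()].
#' @param method Local clustering method.
#' @param test_fraction Held-out edge fraction (default 0.5).
#' @param aggregation,similarity Passed to [score_pair()]; `similarity =
#'   NULL` picks dot product for negative sampling and cosine for
#'   hierarchical softmax.
#' @param seed Integer seed controlling the split, the negatives, and
#'   training.
#' @return List of class `p2v_benchmark`: `auc` (persona model), `auc_base`
#'   (single-vector baseline), `n_test`, `n_nodes`, `n_edges`,
#'   `n_personas`, `n_persona_edges`, `config`, `seed`.
#' @export
run_benchmark <- function(g, config = train_config(),
                          method = "connected_components",
                          test_fraction = 0.5, aggregation = "max",
                          similarity = NULL, seed = 1L) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(similarity)) {
    similarity <- if (config$objective == "hs") "cosine" else "dot"
  }
  seed <- as.integer(seed)
  split <- split_edges(g, test_fraction = test_fraction, seed = seed)
  negatives <- sample_negative_edges(g, nrow(split$test_edges),
                                     seed = seed + 1L)
  split$negative_edges <- negatives
  fit <- persona2vec(split$train_graph, config = config, method = method,
                     seed = seed + 2L)

  score_all <- function(emb, v2p, pairs) {
    vapply(seq_len(nrow(pairs)), function(i) {
      score_pair(emb, v2p, pairs[i, 1L], pairs[i, 2L],
                 aggregation = aggregation, similarity = similarity)
    }, numeric(1L))
  }
  pos <- score_all(fit$persona_embedding, fit$mapping$v2p, split$test_edges)
  neg <- score_all(fit$persona_embedding, fit$mapping$v2p, negatives)
  pos_b <- score_all(fit$base_embedding, NULL, split$test_edges)
  neg_b <- score_all(fit$base_embedding, NULL, negatives)

  kind <- igraph::E(fit$persona_graph$graph)$kind
  structure(
    list(auc = roc_auc(pos, neg), auc_base = roc_auc(pos_b, neg_b),
         n_test = nrow(split$test_edges),
         n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
         n_personas = igraph::vcount(fit$persona_graph$graph),
         n_persona_edges = sum(kind == "persona"),
         config = config, seed = seed),
    class = "p2v_benchmark"
  )
}

#' @export
print.p2v_benchmark <- function(x, ...) {
  cat(sprintf(paste0(
    "link-prediction benchmark: AUC %.3f (personas) vs %.3f (base), ",
    "%d test edges\n|V| = %d, |E| = %d, |V_p| = %d, |E_p| = %d\n"),
    x$auc, x$auc_base, x$n_test, x$n_nodes, x$n_edges, x$n_personas,
    x$n_persona_edges))
  invisible(x)
}
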
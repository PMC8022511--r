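#' Ego-network of a node
#'
#' The subgraph induced on a node's neighbours with the ego itself removed.
#' For directed graphs the neighbour set is the union of in- and
#' out-neighbours and the induced subgraph is returned as an undirected
#' graph, since local clustering of structural contexts ignores direction.
#'
#' @param g A canonical graph.
#' @param v A node id present in `g`.
#' @return An undirected graph on the neighbours of `v`.
#' @export
ego_network <- function(g, v) {
  if (!v %in% igraph::V(g)$name) {
    stop("node not in graph: ", v, call. = FALSE)
  }
  nbrs <- unique(igraph::neighbors(g, v, mode = "all")$name)
  sub <- igraph::induced_subgraph(g, nbrs)
  if (igraph::is_directed(sub)) {
    sub <- igraph::as_undirected(sub, mode = "collapse",
                                 edge.attr.comb = list(weight = "first"))
  }
  sub
}

#' Local clusters of an ego-network
#'
#' Partitions the nodes of an ego-network into non-overlapping local
#' clusters.  `connected_components` (the default throughout the package)
#' treats every connected component as one cluster and is well suited to
#' sparse graphs; `louvain` and `label_propagation` run the corresponding
#' modularity / propagation clusterers and are preferable on dense graphs
#' whose ego-networks rarely disconnect.  Any other partitioner can be
#' supplied as a function taking a graph and returning a list of
#' character vectors.
#'
#' Clusters are returned in a deterministic order, sorted by their smallest
#' member id.
#'
#' @param ego_net A graph, typically from [ego_network()].
#' @param method `"connected_components"`, `"louvain"`,
#'   `"label_propagation"`, or a function.
#' @param seed Optional integer seed for the stochastic clusterers.
#' @return A list of character vectors partitioning the nodes of `ego_net`;
#'   an empty list for an empty ego-network.
#' @export
local_clusters <- function(ego_net, method = "connected_components",
                           seed = NULL) {
  if (igraph::vcount(ego_net) == 0L) return(list())
  if (is.function(method)) {
    cl <- method(ego_net)
  } else {
    method <- match.arg(method,
                        c("connected_components", "louvain",
                          "label_propagation"))
    membership <- switch(method,
      connected_components = igraph::components(ego_net, mode = "weak")$membership,
      louvain = with_seed(seed, igraph::membership(
        igraph::cluster_louvain(ego_net))),
      label_propagation = with_seed(seed, igraph::membership(
        igraph::cluster_label_prop(ego_net)))
    )
    cl <- split(igraph::V(ego_net)$name, membership)
  }
  cl <- lapply(unname(cl), as.character)
  covered <- sort(unlist(cl))
  if (!identical(covered, sort(igraph::V(ego_net)$name))) {
    stop("clustering did not partition the ego-network nodes", call. = FALSE)
  }
  cl[order(vapply(cl, min, character(1L)))]
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

persona_id <- function(node, k) sprintf("%s#%d", node, k)

#' Split nodes into personas
#'
#' Runs ego-splitting over every node of the graph: the node's ego-network
#' is clustered with [local_clusters()] and one persona is created per local
#' cluster.  A node whose ego-network forms a single cluster keeps a single
#' persona; an isolated node gets one persona with an empty cluster so the
#' mapping is total.
#'
#' Persona ids are derived deterministically as `"<node>#<k>"` where `k`
#' indexes the node's clusters in their deterministic order.
#'
#' @param g A canonical graph.
#' @inheritParams local_clusters
#' @return A `persona_mapping`: a list with `v2p` (node id -> character
#'   vector of persona ids), `p2c` (persona id -> character vector of
#'   original-graph nodes, the persona's local cluster) and `p2n` (persona
#'   id -> parent node id).
#' @export
split_personas <- function(g, method = "connected_components", seed = NULL) {
  nodes <- sort(igraph::V(g)$name)
  v2p <- vector("list", length(nodes))
  names(v2p) <- nodes
  p2c <- list()
  p2n <- character(0L)
  for (v in nodes) {
    ego <- ego_network(g, v)
    if (igraph::vcount(ego) == 0L) {
      pid <- persona_id(v, 1L)
      v2p[[v]] <- pid
      p2c[[pid]] <- character(0L)
      p2n[[pid]] <- v
      next
    }
    cl <- local_clusters(ego, method = method, seed = seed)
    pids <- persona_id(v, seq_along(cl))
    v2p[[v]] <- pids
    for (k in seq_along(cl)) {
      p2c[[pids[k]]] <- cl[[k]]
      p2n[[pids[k]]] <- v
    }
  }
  structure(list(v2p = v2p, p2c = p2c, p2n = p2n),
            class = "persona_mapping")
}

#' @export
print.persona_mapping <- function(x, ...) {
  np <- lengths(x$v2p)
  cat(sprintf("persona_mapping: %d nodes -> %d personas (%d nodes split)\n",
              length(x$v2p), length(x$p2c), sum(np > 1L)))
  invisible(x)
}

#' Build the persona graph
#'
#' Replaces every node by its personas and rewires the graph.  Each original
#' edge (v_i, v_j, w) is inherited by the unique persona of v_i whose local
#' cluster contains v_j and the unique persona of v_j whose cluster contains
#' v_i; an undirected original edge becomes two directed edges of weight w,
#' a directed one keeps its single direction.  After all original edges are
#' placed, the original out-strength k_i^o of every persona is recorded, and
#' persona edges are added between every ordered pair of personas of the
#' same node with weight `lambda * k_i^o` of the source persona.  Weighting
#' persona edges by the out-strength makes the probability of escaping a
#' persona through an original edge equal to 1 / (1 + (n_p - 1) * lambda),
#' independent of k_i^o.
#'
#' @param g A canonical graph.
#' @param pm A `persona_mapping` built from `g` with [split_personas()].
#' @param lambda Non-negative persona-edge strength; default 0.5.
#' @param allow_zero_lambda `lambda = 0` produces zero-weight persona edges,
#'   which random walks treat as absent and which disconnect the persona
#'   graph; it must be enabled explicitly.
#' @return A `persona_graph`: list with `graph` (directed weighted igraph
#'   whose edges carry a `kind` attribute, `"original"` or `"persona"`),
#'   `lambda`, `v2p`, `p2c`, and `k_out_original` (named vector of original
#'   out-strengths per persona).
#' @export
build_persona_graph <- function(g, pm, lambda = 0.5,
                                allow_zero_lambda = FALSE) {
  stopifnot(inherits(pm, "persona_mapping"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  if (lambda == 0 && !allow_zero_lambda) {
    stop("lambda = 0 disconnects the persona graph; ",
         "set allow_zero_lambda = TRUE to override", call. = FALSE)
  }
  # owner lookup: which persona of v owns neighbour u
  keys <- character(0L); vals <- character(0L)
  for (pid in names(pm$p2c)) {
    cluster <- pm$p2c[[pid]]
    if (length(cluster) == 0L) next
    v <- pm$p2n[[pid]]
    keys <- c(keys, paste(v, cluster, sep = "\r"))
    vals <- c(vals, rep(pid, length(cluster)))
  }
  owner <- stats::setNames(vals, keys)

  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  directed <- igraph::is_directed(g)
  if (nrow(el) > 0L) {
    p_src <- unname(owner[paste(el[, 1L], el[, 2L], sep = "\r")])
    p_dst <- unname(owner[paste(el[, 2L], el[, 1L], sep = "\r")])
    if (anyNA(p_src) || anyNA(p_dst)) {
      stop("internal consistency error: an edge endpoint matched no local ",
           "cluster (ego-network partition violated)", call. = FALSE)
    }
    if (directed) {
      e_from <- p_src; e_to <- p_dst; e_w <- w
    } else {
      e_from <- c(p_src, p_dst); e_to <- c(p_dst, p_src); e_w <- c(w, w)
    }
  } else {
    e_from <- e_to <- character(0L); e_w <- numeric(0L)
  }

  personas <- names(pm$p2c)
  k_out <- stats::setNames(numeric(length(personas)), personas)
  if (length(e_from) > 0L) {
    s <- tapply(e_w, e_from, sum)
    k_out[names(s)] <- s
  }

  pe_from <- character(0L); pe_to <- character(0L); pe_w <- numeric(0L)
  for (v in names(pm$v2p)) {
    pids <- pm$v2p[[v]]
    n_p <- length(pids)
    if (n_p < 2L) next
    pairs <- expand.grid(src = pids, dst = pids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$src != pairs$dst, , drop = FALSE]
    pe_from <- c(pe_from, pairs$src)
    pe_to <- c(pe_to, pairs$dst)
    pe_w <- c(pe_w, lambda * k_out[pairs$src])
  }

  edges <- data.frame(
    from = c(e_from, pe_from),
    to = c(e_to, pe_to),
    weight = c(e_w, pe_w),
    kind = c(rep("original", length(e_from)), rep("persona", length(pe_from))),
    stringsAsFactors = FALSE
  )
  pg <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = personas, stringsAsFactors = FALSE)
  )
  structure(
    list(graph = pg, lambda = lambda, v2p = pm$v2p, p2c = pm$p2c,
         p2n = pm$p2n, k_out_original = k_out),
    class = "persona_graph"
  )
}

#' @export
print.persona_graph <- function(x, ...) {
  kind <- igraph::E(x$graph)$kind
  cat(sprintf(
    "persona_graph: %d personas, %d original + %d persona edges (lambda = %g)\n",
    igraph::vcount(x$graph), sum(kind == "original"), sum(kind == "persona"),
    x$lambda
  ))
  invisible(x)
}

#' Escape probability of a persona
#'
#' Probability that an unbiased (weight-proportional) random walker standing
#' on a persona leaves through an original edge rather than a persona edge:
#' the ratio of original out-weight to total out-weight.  With persona-edge
#' weight `lambda * k_i^o` this equals `1 / (1 + (n_p - 1) * lambda)` for
#' every persona of a node with n_p personas, regardless of its degree.
#'
#' @param pg A `persona_graph`.
#' @param persona A persona id.
#' @return A probability in \[0, 1\].
#' @export
escape_probability <- function(pg, persona) {
  stopifnot(inherits(pg, "persona_graph"))
  if (!persona %in% igraph::V(pg$graph)$name) {
    stop("unknown persona: ", persona, call. = FALSE)
  }
  eids <- igraph::incident(pg$graph, persona, mode = "out")
  w <- igraph::E(pg$graph)$weight[as.integer(eids)]
  kind <- igraph::E(pg$graph)$kind[as.integer(eids)]
  total <- sum(w)
  if (total <= 0) {
    stop("persona ", persona, " has no positive-weight outgoing edge; ",
         "escape probability undefined", call. = FALSE)
  }
  sum(w[kind == "original"]) / total
}

#' Persona counts per node
#'
#' @param pm A `persona_mapping` or `persona_graph`.
#' @return Named integer vector: number of personas of each original node.
#' @export
persona_counts <- function(pm) {
  stopifnot(inherits(pm, c("persona_mapping", "persona_graph")))
  vapply(pm$v2p, length, integer(1L))
}

#' Export a persona graph and its mappings as plain text
#'
#' Writes three files: `<prefix>.personas.edgelist` (directed weighted edge
#' list with a fourth `original|persona` column), `<prefix>.v2p.tsv`
#' (node, persona), and `<prefix>.p2c.tsv` (persona, cluster member).
#'
#' @param pg A `persona_graph`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_persona_graph <- function(pg, prefix) {
  stopifnot(inherits(pg, "persona_graph"))
  el <- igraph::as_edgelist(pg$graph, names = TRUE)
  p_edges <- paste0(prefix, ".personas.edgelist")
  writeLines(paste(el[, 1L], el[, 2L],
                   format(igraph::E(pg$graph)$weight, trim = TRUE),
                   igraph::E(pg$graph)$kind), p_edges)
  p_v2p <- paste0(prefix, ".v2p.tsv")
  v2p_rows <- unlist(lapply(names(pg$v2p), function(v) {
    paste(v, pg$v2p[[v]], sep = "\t")
  }))
  writeLines(v2p_rows, p_v2p)
  p_p2c <- paste0(prefix, ".p2c.tsv")
  p2c_rows <- unlist(lapply(names(pg$p2c), function(p) {
    cl <- pg$p2c[[p]]
    if (length(cl) == 0L) paste(p, "", sep = "\t") else paste(p, cl, sep = "\t")
  }))
  writeLines(p2c_rows, p_p2c)
  invisible(c(p_edges, p_v2p, p_p2c))
}
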
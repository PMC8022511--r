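#' Planted overlapping-community graph
#'
#' Generates a union of cliques in which designated bridge nodes are shared
#' members of several cliques — the canonical picture of pervasively
#' overlapping community structure.  Each clique has `clique_size` members
#' (bridges count as members of every clique they join).  Optional noise
#' edges are added independently with probability `noise_p` between
#' non-bridge nodes of different cliques.
#'
#' When `bridge_assignments` is omitted, `n_bridges` bridges are created
#' and assigned to distinct clique pairs sampled from the cross pairs of a
#' random balanced bipartition of the cliques, so the chosen pairs form a
#' triangle-free graph over the cliques.  Triangle-freeness is what makes
#' recovery exact: two bridges
#' whose clique pairs share a clique are adjacent, and if a third bridge
#' spans their remaining two cliques its ego-network components would merge
#' through that adjacency.  Without such triangles (and without noise),
#' every node's ego-network has exactly one connected component per planted
#' membership, so connected-component ego-splitting recovers the membership
#' counts exactly.  At most `floor(n_cliques^2 / 4)` bridges fit this
#' constraint.  Explicit `bridge_assignments` are not checked for
#' triangles.
#'
#' @param n_cliques Number of cliques.
#' @param clique_size Members per clique (>= 3).
#' @param n_bridges Number of bridge nodes (ignored when
#'   `bridge_assignments` given).
#' @param bridge_assignments Optional named list: bridge id -> integer
#'   vector of >= 2 clique indices.
#' @param noise_p Probability of an inter-clique noise edge, in \[0, 1).
#' @param seed Integer seed.
#' @return List with `graph` (canonical undirected graph) and `memberships`
#'   (named list: node id -> integer vector of clique indices).
#' @export
planted_overlap_graph <- function(n_cliques, clique_size, n_bridges = 0,
                                  bridge_assignments = NULL, noise_p = 0,
                                  seed = 1L) {
  stopifnot(n_cliques >= 1, clique_size >= 3, noise_p >= 0, noise_p < 1)
  with_seed(seed, {
    if (is.null(bridge_assignments)) {
      bridge_assignments <- list()
      if (n_bridges > 0) {
        stopifnot(n_cliques >= 2)
        if (n_bridges > floor(n_cliques^2 / 4)) {
          stop("more bridges than triangle-free clique pairs", call. = FALSE)
        }
        # cross pairs of a random balanced bipartition of the cliques are
        # triangle-free and reach the floor(n^2/4) capacity
        side_a <- sort(sample.int(n_cliques, floor(n_cliques / 2)))
        side_b <- setdiff(seq_len(n_cliques), side_a)
        cross <- as.matrix(expand.grid(side_a, side_b))
        pick <- sample.int(nrow(cross), n_bridges)
        for (b in seq_len(n_bridges)) {
          bridge_assignments[[sprintf("b%02d", b)]] <-
            as.integer(sort(cross[pick[b], ]))
        }
      }
    }
    for (cl in bridge_assignments) {
      if (length(unique(cl)) < 2L || any(cl < 1L) || any(cl > n_cliques)) {
        stop("each bridge must belong to >= 2 distinct valid cliques",
             call. = FALSE)
      }
    }
    bridges <- names(bridge_assignments)
    members <- vector("list", n_cliques)
    for (k in seq_len(n_cliques)) {
      in_k <- bridges[vapply(bridge_assignments,
                             function(cl) k %in% cl, logical(1L))]
      if (length(in_k) >= clique_size) {
        stop("clique ", k, " has no room for non-bridge members",
             call. = FALSE)
      }
      own <- sprintf("c%02dn%02d", k, seq_len(clique_size - length(in_k)))
      members[[k]] <- c(own, in_k)
    }
    edges <- do.call(rbind, lapply(members, function(mm) {
      t(utils::combn(sort(mm), 2L))
    }))
    if (noise_p > 0) {
      plain <- lapply(members, function(mm) setdiff(mm, bridges))
      cross <- do.call(rbind, unlist(lapply(seq_len(n_cliques - 1L), function(i) {
        lapply((i + 1L):n_cliques, function(j) {
          as.matrix(expand.grid(plain[[i]], plain[[j]],
                                stringsAsFactors = FALSE))
        })
      }), recursive = FALSE))
      if (!is.null(cross) && nrow(cross) > 0L) {
        keep <- stats::runif(nrow(cross)) < noise_p
        edges <- rbind(edges, cross[keep, , drop = FALSE])
      }
    }
    g <- canonicalize_graph(igraph::graph_from_edgelist(as.matrix(edges),
                                                        directed = FALSE))
    memberships <- list()
    for (k in seq_len(n_cliques)) {
      for (v in members[[k]]) {
        memberships[[v]] <- c(memberships[[v]], k)
      }
    }
    list(graph = g, memberships = memberships[sort(names(memberships))])
  })
}

#' Six-node toy graph with one two-role node
#'
#' A small graph over nodes A-F in which node C bridges two communities:
#' its ego-network splits into the components \{A, B\} and \{D, E, F\}, so
#' ego-splitting gives C two personas while every other node keeps one.
#' Both communities are internally complete (triangle A-B-C and clique
#' C-D-E-F).
#'
#' @return A canonical undirected graph.
#' @export
fig1_toy <- function() {
  edges <- matrix(c(
    "C", "A", "C", "B", "A", "B",
    "C", "D", "C", "E", "C", "F",
    "D", "E", "E", "F", "D", "F"
  ), ncol = 2L, byrow = TRUE)
  canonicalize_graph(igraph::graph_from_edgelist(edges, directed = FALSE))
}

#' Zachary's Karate club graph
#'
#' The classic 34-member karate-club friendship network (34 nodes, 78
#' edges), shipped as a plain-text edge list with the customary 1-based
#' node labels.  Several members bridge the club's factions; member 1
#' splits into four personas under connected-component ego-splitting.
#'
#' @return A canonical undirected graph.
#' @export
karate_club <- function() {
  path <- system.file("extdata", "karate.edgelist",
                      package = "persona2vec", mustWork = TRUE)
  read_edgelist(path, directed = FALSE, weighted = FALSE)
}
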
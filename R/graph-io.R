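#' Read a plain-text edge list
#'
#' Parses the whitespace-separated edge-list dialect used by the large public
#' network repositories: one edge per line, `#`-prefixed comment lines
#' ignored, an optional third column carrying a positive edge weight.  The
#' parsed graph is canonicalized: self-loops are dropped (their count is
#' reported via [message()]), duplicate edges collapse to the first
#' occurrence, and undirected edges are stored once under a canonical
#' endpoint order.  Unweighted edges receive weight 1 so that downstream
#' random walks always operate on a weighted graph.
#'
#' Node identifiers are kept as opaque strings; `"007"` and `"7"` are
#' different nodes.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; interpret each line as a directed edge.
#' @param weighted Logical; require and parse a third weight column.
#' @return An [igraph::igraph] graph with character vertex names and a
#'   positive `weight` edge attribute.
#' @seealso [write_edgelist()], [largest_connected_component()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), f)
#' g <- read_edgelist(f)
#' igraph::vcount(g)
#' @export
read_edgelist <- function(path, directed = FALSE, weighted = FALSE) {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no edges found in ", path, call. = FALSE)
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  want <- if (weighted) 3L else 2L
  nt <- lengths(toks)
  bad <- which(nt != want)
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed line %d in %s: expected %d fields, found %d",
      idx[bad[1L]], path, want, nt[bad[1L]]
    ), call. = FALSE)
  }
  m <- do.call(rbind, toks)
  w <- if (weighted) suppressWarnings(as.numeric(m[, 3L])) else rep(1, nrow(m))
  if (anyNA(w) || any(w <= 0)) {
    first <- which(is.na(w) | w <= 0)[1L]
    stop(sprintf(
      "invalid weight on line %d in %s: weights must be positive numbers",
      idx[first], path
    ), call. = FALSE)
  }
  edges <- data.frame(
    from = m[, 1L], to = m[, 2L], weight = w,
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = directed)
  canonicalize_graph(g)
}

#' Canonicalize a graph
#'
#' Removes self-loops (reporting their count), collapses multi-edges keeping
#' the first occurrence's weight, and guarantees a positive `weight` edge
#' attribute and character vertex names.  All package operations assume
#' canonical input.
#'
#' @param g An [igraph::igraph] graph.
#' @return A simple graph with `weight` edge attribute.
#' @export
canonicalize_graph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  }
  if (any(igraph::E(g)$weight <= 0)) {
    stop("edge weights must be strictly positive", call. = FALSE)
  }
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0L) {
    message(n_loops, " self-loop(s) removed during canonicalization")
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "first"))
}

#' Write a graph as a plain-text edge list
#'
#' Writes the same dialect [read_edgelist()] consumes: whitespace-separated
#' `from to` lines, with a third weight column when the graph carries
#' non-unit weights (or when `weighted = TRUE` forces it).  Reading the
#' result back with the matching `weighted` flag and directedness
#' reproduces the graph exactly.
#'
#' @param g A canonical graph.
#' @param path Output file path.
#' @param header Optional comment line (written with a leading `#`).
#' @param weighted Write the weight column; defaults to whether any weight
#'   differs from 1.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, header = NULL, weighted = NULL) {
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  if (is.null(weighted)) weighted <- any(w != 1)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  lines <- if (weighted) {
    paste(el[, 1L], el[, 2L], format(w, trim = TRUE, digits = 17))
  } else {
    paste(el[, 1L], el[, 2L])
  }
  writeLines(lines, con)
  invisible(path)
}

#' Largest (weakly) connected component
#'
#' Induced subgraph on the largest connected component of an undirected
#' graph, or the largest weakly connected component of a directed graph.
#' Ties in component size are broken deterministically in favour of the
#' component containing the lexicographically smallest node id.
#'
#' @param g A non-empty graph.
#' @return The induced subgraph on the winning component.
#' @export
largest_connected_component <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) {
    stop("cannot take the largest component of an empty graph", call. = FALSE)
  }
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest lexicographic member decides among equally sized components
    min_member <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1L))
    best <- best[order(min_member)[1L]]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}
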
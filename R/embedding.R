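#' Training configuration
#'
#' Bundles the hyper-parameters of the two embedding stages.  The defaults
#' follow the method's recommended settings: base walks of length `t_b = 40`,
#' `gamma_b = 10` per node with window `w_b = 5`; persona-graph fine-tuning
#' walks of length `t_p = 80`, `gamma_p = 5` per node with the narrower
#' window `w_p = 2` to capture the micro-structure of the persona graph
#' (the product `t * gamma` is kept constant across the two stages so both
#' see the same amount of trajectory).  Initial learning rate
#' `alpha = 0.025` decaying linearly to `alpha * 1e-4`; one fine-tuning
#' epoch (`epochs = 1`); `negatives = 5` noise samples per pair drawn from
#' the unigram distribution raised to 3/4.
#'
#' @param d Embedding dimension.
#' @param gamma_b,t_b,w_b Walks per node, walk length and window size for
#'   the base embedding of the original graph.
#' @param gamma_p,t_p,w_p The same for persona-graph fine-tuning.
#' @param alpha Initial learning rate.
#' @param lambda Persona-edge strength passed to [build_persona_graph()].
#' @param epochs Fine-tuning epochs over the persona walk corpus.
#' @param negatives Negative samples per skip-gram pair.
#' @param objective `"ns"` (negative sampling, default) or `"hs"`
#'   (hierarchical softmax).
#' @return A list of class `train_config`.
#' @export
train_config <- function(d = 128, gamma_b = 10, t_b = 40, w_b = 5,
                         gamma_p = 5, t_p = 80, w_p = 2,
                         alpha = 0.025, lambda = 0.5, epochs = 1,
                         negatives = 5, objective = c("ns", "hs")) {
  objective <- match.arg(objective)
  stopifnot(d >= 1, gamma_b >= 1, t_b >= 1, w_b >= 1,
            gamma_p >= 1, t_p >= 1, w_p >= 1,
            alpha > 0, lambda >= 0, epochs >= 0, negatives >= 1)
  structure(
    list(d = as.integer(d), gamma_b = as.integer(gamma_b),
         t_b = as.integer(t_b), w_b = as.integer(w_b),
         gamma_p = as.integer(gamma_p), t_p = as.integer(t_p),
         w_p = as.integer(w_p), alpha = alpha, lambda = lambda,
         epochs = as.integer(epochs), negatives = as.integer(negatives),
         objective = objective),
    class = "train_config"
  )
}

#' Generate a random-walk corpus
#'
#' First-order random walks with next-step probability proportional to
#' out-edge weight (the unbiased node2vec walk, p = q = 1).  `gamma` walks
#' are started from every node; within each pass the start order is
#' shuffled.  A node with no positive-weight out-edge truncates the walk,
#' so isolated nodes yield length-1 walks.  Zero-weight edges are treated
#' as absent.  Undirected graphs are walked along both edge directions.
#'
#' @param g An igraph graph or a `persona_graph`.
#' @param gamma Walks per start node.
#' @param t Walk length (number of visited nodes, including the start).
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return A `walk_corpus`: list with `walks` (list of character vectors),
#'   `ids` (vocabulary), `t`, `gamma`, `seed`.
#' @export
generate_walks <- function(g, gamma, t, seed = 1L) {
  if (inherits(g, "persona_graph")) g <- g$graph
  stopifnot(igraph::is_igraph(g), igraph::vcount(g) > 0L)
  ids <- igraph::V(g)$name
  n <- length(ids)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  if (!igraph::is_directed(g) && nrow(el) > 0L) {
    el <- rbind(el, el[, 2:1, drop = FALSE])
    w <- c(w, w)
  }
  pos <- w > 0
  el <- el[pos, , drop = FALSE]
  w <- w[pos]
  adj <- vector("list", n)
  wts <- vector("list", n)
  src <- if (nrow(el) > 0L) split(seq_len(nrow(el)), factor(el[, 1L], levels = seq_len(n))) else
    rep(list(integer(0L)), n)
  for (i in seq_len(n)) {
    rows <- src[[i]]
    adj[[i]] <- as.integer(el[rows, 2L] - 1L)
    wts[[i]] <- as.numeric(w[rows])
  }
  raw <- random_walks_cpp(adj, wts, as.integer(gamma), as.integer(t),
                          as.integer(seed))
  walks <- lapply(raw, function(ix) ids[ix + 1L])
  structure(list(walks = walks, ids = ids, t = as.integer(t),
                 gamma = as.integer(gamma), seed = as.integer(seed)),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks (gamma = %d, t = %d) over %d ids\n",
              length(x$walks), x$gamma, x$t, length(x$ids)))
  invisible(x)
}

#' Construct an embedding matrix
#'
#' @param ids Ordered id vector.
#' @param input,output Numeric matrices, one row per id ('input' vectors
#'   Phi and 'output' vectors Phi'); for hierarchical-softmax models the
#'   output rows are the Huffman inner-node vectors instead.
#' @param objective `"ns"` or `"hs"`.
#' @return An `embedding_matrix`.
#' @export
embedding_matrix <- function(ids, input, output, objective = "ns") {
  stopifnot(nrow(input) == length(ids), ncol(input) == ncol(output),
            all(is.finite(input)), all(is.finite(output)))
  rownames(input) <- ids
  structure(list(ids = ids, input = input, output = output,
                 d = ncol(input), objective = objective),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("embedding_matrix: %d ids, d = %d (%s)\n",
              length(x$ids), x$d, x$objective))
  invisible(x)
}

corpus_indices <- function(corpus, ids) {
  idx <- lapply(corpus$walks, function(wk) {
    m <- match(wk, ids)
    if (anyNA(m)) stop("corpus contains ids missing from the vocabulary",
                       call. = FALSE)
    m - 1L
  })
  idx
}

corpus_counts <- function(walks_idx, vocab) {
  tab <- tabulate(unlist(walks_idx) + 1L, nbins = vocab)
  # every id keeps a tiny noise mass so sampling stays well defined
  pmax(tab, 1L)
}

#' Train skip-gram with negative sampling
#'
#' Optimizes the skip-gram objective over a walk corpus: every (centre,
#' context) pair within `w` positions raises the score of its pair and
#' lowers the score of `negatives` noise ids drawn from the corpus unigram
#' distribution raised to 3/4.  The learning rate decays linearly from
#' `alpha` to `alpha * 1e-4`.  When `init` is supplied, both input and
#' output vectors start from it (fine-tuning); otherwise input vectors are
#' initialized uniformly in (-0.5/d, 0.5/d) and output vectors at zero.
#' Training is single-threaded and reproducible given `seed`.
#'
#' @param corpus A `walk_corpus`.
#' @param d Embedding dimension (ignored when `init` is given).
#' @param w Context window size.
#' @param alpha Initial learning rate.
#' @param epochs Passes over the corpus; 0 with `init` returns `init`
#'   restricted to the corpus vocabulary.
#' @param negatives Negative samples per pair.
#' @param seed Integer seed.
#' @param init Optional `embedding_matrix` whose ids cover the corpus
#'   vocabulary.
#' @return An `embedding_matrix` over the corpus vocabulary.
#' @export
train_sgns <- function(corpus, d = 128, w = 5, alpha = 0.025, epochs = 1,
                       negatives = 5, seed = 1L, init = NULL) {
  stopifnot(inherits(corpus, "walk_corpus"), length(corpus$walks) > 0L)
  ids <- corpus$ids
  init_in <- init_out <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "embedding_matrix"))
    if (!all(ids %in% init$ids)) {
      stop("init embedding does not cover the corpus vocabulary",
           call. = FALSE)
    }
    rows <- match(ids, init$ids)
    init_in <- init$input[rows, , drop = FALSE]
    init_out <- init$output[rows, , drop = FALSE]
    d <- init$d
  }
  walks_idx <- corpus_indices(corpus, ids)
  counts <- corpus_counts(walks_idx, length(ids))
  fit <- sgns_train_cpp(walks_idx, length(ids), as.integer(d),
                        as.integer(w), as.integer(negatives),
                        alpha, as.integer(epochs), as.integer(seed),
                        init_in, init_out, as.numeric(counts))
  embedding_matrix(ids, fit$input, fit$output, objective = "ns")
}

#' Huffman codes from frequencies
#'
#' Builds the Huffman tree over a frequency vector and returns, per leaf,
#' its binary code and the inner nodes along the root-to-leaf path.  More
#' frequent ids receive shorter codes.  Ties are broken deterministically
#' by insertion order.
#'
#' @param freq Positive frequency vector (one entry per vocabulary id).
#' @return List with `codes` (list of 0/1 integer vectors), `points` (list
#'   of 0-based inner-node index vectors, root first) and `n_inner`.
#' @export
huffman_codes <- function(freq) {
  stopifnot(is.numeric(freq), length(freq) >= 1L, all(freq > 0))
  n <- length(freq)
  if (n == 1L) {
    return(list(codes = list(integer(0L)), points = list(integer(0L)),
                n_inner = 1L))
  }
  # two-queue construction: leaves sorted ascending in one queue, newly
  # merged inner nodes (created in nondecreasing count order) in the other
  ord <- order(freq)
  count <- c(freq[ord], rep(NA_real_, n - 1L))
  parent <- integer(2L * n - 1L)
  binary <- integer(2L * n - 1L)
  pos_leaf <- 1L
  pos_inner <- n + 1L
  next_free <- n
  take_min <- function() {
    leaf_ok <- pos_leaf <= n
    inner_ok <- pos_inner <= next_free
    use_leaf <- leaf_ok &&
      (!inner_ok || count[pos_leaf] <= count[pos_inner])
    if (use_leaf) {
      node <- pos_leaf; pos_leaf <<- pos_leaf + 1L
    } else {
      node <- pos_inner; pos_inner <<- pos_inner + 1L
    }
    node
  }
  for (k in seq_len(n - 1L)) {
    a <- take_min()
    b <- take_min()
    next_free <- next_free + 1L
    count[next_free] <- count[a] + count[b]
    parent[a] <- next_free
    parent[b] <- next_free
    binary[b] <- 1L
  }
  root <- 2L * n - 1L
  # map back from the sorted leaf order to the input order
  leaf_of <- integer(n)
  leaf_of[ord] <- seq_len(n)
  codes <- vector("list", n)
  points <- vector("list", n)
  for (v in seq_len(n)) {
    code <- integer(0L)
    path <- integer(0L)
    node <- leaf_of[v]
    while (node != root) {
      code <- c(binary[node], code)
      node <- parent[node]
      path <- c(node - n, path)  # inner nodes numbered from 1
    }
    codes[[v]] <- code
    points[[v]] <- as.integer(path - 1L)  # 0-based, root first
  }
  list(codes = codes, points = points, n_inner = n - 1L)
}

#' Train skip-gram with hierarchical softmax
#'
#' As [train_sgns()] but with a Huffman-tree hierarchical-softmax output
#' layer: each context prediction walks the root-to-leaf path of the
#' context id, performing one logistic update per inner node.  The Huffman
#' tree is built from the corpus unigram counts, so frequent ids get short
#' codes.  The returned `output` matrix holds the inner-node vectors.
#'
#' @inheritParams train_sgns
#' @return An `embedding_matrix` with `objective = "hs"`.
#' @export
train_hs <- function(corpus, d = 128, w = 5, alpha = 0.025, epochs = 1,
                     seed = 1L, init = NULL) {
  stopifnot(inherits(corpus, "walk_corpus"), length(corpus$walks) > 0L)
  ids <- corpus$ids
  walks_idx <- corpus_indices(corpus, ids)
  counts <- corpus_counts(walks_idx, length(ids))
  huff <- huffman_codes(counts)
  init_in <- init_inner <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "embedding_matrix"))
    if (!all(ids %in% init$ids)) {
      stop("init embedding does not cover the corpus vocabulary",
           call. = FALSE)
    }
    init_in <- init$input[match(ids, init$ids), , drop = FALSE]
    if (identical(init$objective, "hs") &&
        nrow(init$output) == huff$n_inner) {
      init_inner <- init$output
    }
    d <- init$d
  }
  fit <- hs_train_cpp(walks_idx, length(ids), as.integer(d), as.integer(w),
                      alpha, as.integer(epochs), as.integer(seed),
                      huff$codes, huff$points, huff$n_inner,
                      init_in, init_inner)
  structure(list(ids = ids, input = `rownames<-`(fit$input, ids),
                 output = fit$output, d = ncol(fit$input),
                 objective = "hs"),
            class = "embedding_matrix")
}

#' Full-softmax co-occurrence probability
#'
#' The modeled probability of id `v_i` co-occurring with id `v_j`:
#' `exp(Phi'_{v_i} . Phi_{v_j})` normalized over the output vectors of the
#' whole vocabulary.  This is the exact objective that negative sampling
#' and hierarchical softmax approximate; it is exposed as a reference
#' quantity for tests and diagnostics, not used in training.
#'
#' @param emb An `embedding_matrix` trained with negative sampling.
#' @param v_i,v_j Ids present in `emb`.
#' @return A probability.
#' @export
softmax_cooccurrence <- function(emb, v_i, v_j) {
  stopifnot(inherits(emb, "embedding_matrix"))
  i <- match(v_i, emb$ids); j <- match(v_j, emb$ids)
  if (is.na(i) || is.na(j)) {
    stop("unknown id: ", if (is.na(i)) v_i else v_j, call. = FALSE)
  }
  scores <- as.numeric(emb$output %*% emb$input[j, ])
  scores <- scores - max(scores)  # overflow guard
  exp(scores[i]) / sum(exp(scores))
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `N d`, then one line per id: the id followed by `d` floats.
#'
#' @param emb An `embedding_matrix`.
#' @param path File path.
#' @return `path` invisibly (writer); an `embedding_matrix` with zero
#'   output vectors (reader — the text format stores input vectors only).
#' @export
write_word2vec <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(emb$ids), emb$d), con)
  lines <- vapply(seq_along(emb$ids), function(i) {
    paste(emb$ids[i], paste(format(emb$input[i, ], trim = TRUE, digits = 17),
                            collapse = " "))
  }, character(1L))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  n <- hdr[1L]; d <- hdr[2L]
  toks <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  ids <- vapply(toks, `[[`, character(1L), 1L)
  input <- do.call(rbind, lapply(toks, function(tk) as.numeric(tk[-1L])))
  stopifnot(ncol(input) == d)
  embedding_matrix(ids, input, matrix(0, n, d))
}
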
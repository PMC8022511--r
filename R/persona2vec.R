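#' Learn multi-role persona embeddings of a graph
#'
#' Full pipeline: (1) a base embedding of the original graph is trained on
#' a random-walk corpus with the base-stage hyper-parameters; (2) the graph
#' is ego-split into a persona graph with [split_personas()] and
#' [build_persona_graph()]; (3) every persona's input and output vectors
#' are initialized from its parent node's base vectors, so all personas of
#' one node start identical and the base co-occurrence scores are preserved
#' exactly at epoch 0; (4) the embedding is fine-tuned on persona-graph
#' walks for a small number of epochs (default 1).  Training the persona
#' graph from scratch instead of fine-tuning loses the global structure of
#' the original graph; fine-tuning mixes both.
#'
#' @param g A canonical graph.
#' @param config A [train_config()].
#' @param method Local clustering method for [local_clusters()].
#' @param seed Integer master seed; all walk generation and training
#'   randomness derives from it.
#' @return A list of class `persona2vec_fit` with elements
#'   `persona_embedding` (an `embedding_matrix` over persona ids),
#'   `base_embedding` (over original node ids), `persona_graph`,
#'   `mapping` (`persona_mapping`), `config`, `seed`.
#' @examples
#' g <- fig1_toy()
#' fit <- persona2vec(g, train_config(d = 8), seed = 42)
#' fit$mapping$v2p[["C"]]
#' @export
persona2vec <- function(g, config = train_config(),
                        method = "connected_components", seed = 1L) {
  stopifnot(inherits(config, "train_config"))
  seed <- as.integer(seed)
  base_corpus <- generate_walks(g, gamma = config$gamma_b, t = config$t_b,
                                seed = seed)
  base_emb <- if (config$objective == "hs") {
    train_hs(base_corpus, d = config$d, w = config$w_b,
             alpha = config$alpha, epochs = 1, seed = seed + 1L)
  } else {
    train_sgns(base_corpus, d = config$d, w = config$w_b,
               alpha = config$alpha, epochs = 1,
               negatives = config$negatives, seed = seed + 1L)
  }

  pm <- split_personas(g, method = method, seed = seed)
  pg <- build_persona_graph(g, pm, lambda = config$lambda,
                            allow_zero_lambda = config$lambda == 0)

  persona_ids <- igraph::V(pg$graph)$name
  parents <- unname(pg$p2n[persona_ids])
  rows <- match(parents, base_emb$ids)
  init <- embedding_matrix(
    persona_ids,
    base_emb$input[rows, , drop = FALSE],
    if (config$objective == "hs") {
      matrix(0, length(persona_ids), base_emb$d)
    } else {
      base_emb$output[rows, , drop = FALSE]
    },
    objective = config$objective
  )

  persona_emb <- if (config$epochs == 0L) {
    init
  } else {
    persona_corpus <- generate_walks(pg, gamma = config$gamma_p,
                                     t = config$t_p, seed = seed + 2L)
    if (config$objective == "hs") {
      train_hs(persona_corpus, w = config$w_p, alpha = config$alpha,
               epochs = config$epochs, seed = seed + 3L, init = init)
    } else {
      train_sgns(persona_corpus, w = config$w_p, alpha = config$alpha,
                 epochs = config$epochs, negatives = config$negatives,
                 seed = seed + 3L, init = init)
    }
  }

  structure(
    list(persona_embedding = persona_emb, base_embedding = base_emb,
         persona_graph = pg, mapping = pm, config = config, seed = seed),
    class = "persona2vec_fit"
  )
}

#' @export
print.persona2vec_fit <- function(x, ...) {
  np <- persona_counts(x$mapping)
  cat(sprintf(paste0(
    "persona2vec fit: %d nodes -> %d personas (%d split), d = %d, ",
    "lambda = %g, %s\n"),
    length(x$mapping$v2p), length(x$mapping$p2c), sum(np > 1L),
    x$config$d, x$config$lambda, x$config$objective))
  invisible(x)
}
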
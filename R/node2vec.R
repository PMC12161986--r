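#' Second-order walk bias weight
#'
#' The unnormalized transition weight from `cur_node` to `next_node` given
#' that the walk arrived from `prev_node`: edge weight times `1/p` when
#' stepping back to `prev_node`, `1` when `next_node` is also adjacent to
#' `prev_node`, and `1/q` otherwise. With `p = q = 1` the walk degenerates
#' to a first-order (weight-proportional) walk.
#'
#' @param prev_node,cur_node,next_node protein symbols (`prev_node` may be
#'   `NA` for the first step, in which case the raw edge weight is
#'   returned).
#' @param p,q return and in-out parameters (> 0).
#' @param network an `InteractionNetwork`.
#' @param use_scores use edge scores as weights (default unweighted).
#' @return The bias weight (a single real).
#' @export
second_order_weight <- function(prev_node, cur_node, next_node, p, q, network,
                                use_scores = has_scores(network)) {
  adj <- adjacency_lookup(network)
  edge_w <- function(a, b) {
    key <- paste(min(a, b), max(a, b), sep = "\t")
    w <- adj$weights[[key]]
    if (is.null(w)) NULL else if (use_scores) w else 1
  }
  w <- edge_w(cur_node, next_node)
  cm_assert(!is.null(w), sprintf("%s and %s are not adjacent", cur_node, next_node))
  if (is.na(prev_node)) return(w)
  if (next_node == prev_node) return(w / p)
  if (!is.null(edge_w(prev_node, next_node))) return(w)
  w / q
}

adjacency_lookup <- function(net) {
  ed <- net$edges
  w <- if (has_scores(net)) ed$score else rep(1, nrow(ed))
  weights <- as.list(w)
  names(weights) <- paste(ed$from, ed$to, sep = "\t")
  list(weights = weights)
}

# CSR adjacency over nodes indexed 0..n-1 (sorted node order); neighbor
# lists sorted so the C++ walker can binary-search them.
network_csr <- function(net, use_scores = FALSE) {
  nodes <- net$nodes
  idx <- seq_along(nodes) - 1L
  names(idx) <- nodes
  ed <- net$edges
  a <- idx[ed$from]; b <- idx[ed$to]
  w <- if (use_scores && has_scores(net)) ed$score else rep(1, nrow(ed))
  src <- c(a, b); dst <- c(b, a); ww <- c(w, w)
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]; ww <- ww[o]
  offsets <- c(0L, cumsum(tabulate(src + 1L, nbins = length(nodes))))
  list(nodes = nodes, offsets = as.integer(offsets),
       neighbors = as.integer(dst), weights = as.numeric(ww))
}

#' Generate a node2vec walk corpus
#'
#' Runs `r` biased second-order random walks of length `l` from every node
#' of the network. Isolated nodes produce length-1 walks. Deterministic
#' given `seed`.
#'
#' @param network an `InteractionNetwork`.
#' @param r walks per node.
#' @param l walk length (number of visited nodes).
#' @param p,q node2vec return / in-out parameters.
#' @param seed integer seed.
#' @param use_scores bias steps by edge scores (default off: the network
#'   is score-filtered upstream and then treated as an unweighted graph).
#' @return A `WalkCorpus`: list with `walks` (list of character vectors)
#'   and `params`.
#' @export
generate_walks <- function(network, r = 10, l = 80, p = 1, q = 1, seed = 1,
                           use_scores = FALSE) {
  cm_assert(length(network$nodes) > 0, "network is empty")
  csr <- network_csr(network, use_scores)
  m <- .cpp_generate_walks(csr$offsets, csr$neighbors, csr$weights,
                           length(csr$nodes), as.integer(r), as.integer(l),
                           p, q, as.numeric(seed))
  walks <- lapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    csr$nodes[row[row >= 0] + 1L]
  })
  structure(list(walks = walks, .token_matrix = m, .vocab = csr$nodes,
                 params = list(num_walks = r, walk_length = l, p = p, q = q,
                               seed = seed, use_scores = use_scores)),
            class = "WalkCorpus")
}

#' @export
print.WalkCorpus <- function(x, ...) {
  cat(sprintf("WalkCorpus: %d walks (r=%d, l=%d, p=%g, q=%g)\n",
              length(x$walks), x$params$num_walks, x$params$walk_length,
              x$params$p, x$params$q))
  invisible(x)
}

#' Skip-gram training configuration
#'
#' @param dimension embedding dimension `d`.
#' @param window symmetric context window size.
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the corpus.
#' @param learning_rate initial learning rate (decays linearly).
#' @param seed integer seed.
#' @return A `SkipGramConfig` list.
#' @export
skipgram_config <- function(dimension = 128, window = 10, negatives = 5,
                            epochs = 5, learning_rate = 0.025, seed = 1) {
  cm_assert(dimension >= 1 && window >= 1 && negatives >= 1,
            "dimension, window and negatives must all be >= 1")
  structure(list(dimension = as.integer(dimension), window = as.integer(window),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = seed),
            class = "SkipGramConfig")
}

#' Train skip-gram embeddings over a walk corpus
#'
#' Skip-gram with negative sampling (unigram^(3/4) noise distribution),
#' single-threaded SGD with linearly decaying learning rate; bit-identical
#' output for identical corpus, config and seed. Vocabulary nodes that
#' never co-occur with anything keep their random initialization (flagged
#' with a message).
#'
#' @param corpus a `WalkCorpus` from [generate_walks()].
#' @param config a [skipgram_config()].
#' @return An `EmbeddingSet` with `modality = "ppi"`.
#' @export
train_skipgram <- function(corpus, config = skipgram_config()) {
  cm_assert(length(corpus$walks) > 0, "walk corpus is empty")
  vocab <- corpus$.vocab
  m <- corpus$.token_matrix
  # nodes appearing only as length-1 walks get no positive updates
  walk_len <- rowSums(m >= 0)
  iso <- unique(m[walk_len == 1L, 1L])
  if (length(iso) > 0)
    message(sprintf("%d node(s) are isolated; their embeddings stay near initialization: %s",
                    length(iso), paste(head(vocab[iso + 1L], 5), collapse = ", ")))
  vec <- .cpp_train_sgns(m, length(vocab), config$dimension, config$window,
                         config$negatives, config$epochs, config$learning_rate,
                         as.numeric(config$seed))
  embedding_set(vocab, vec, modality = "ppi")
}

#' Embed a PPI network (walks + skip-gram), writing a stage directory
#'
#' Composition of [generate_walks()] and [train_skipgram()]; writes
#' `ppi_emb.tsv`, a log file and a provenance record into `outdir`.
#'
#' @param network an `InteractionNetwork`.
#' @param outdir stage directory (created if needed).
#' @param walk_params list overriding [generate_walks()] defaults.
#' @param sg_config a [skipgram_config()].
#' @param seed seed applied to both walks and training when the
#'   sub-configs do not carry their own.
#' @param inputs provenance inputs (paths of upstream artifacts).
#' @return The `EmbeddingSet`, invisibly.
#' @export
ppi_embed <- function(network, outdir, walk_params = list(),
                      sg_config = NULL, seed = 1, inputs = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wp <- utils::modifyList(list(r = 10, l = 80, p = 1, q = 1, seed = seed,
                               use_scores = FALSE), walk_params)
  if (is.null(sg_config)) sg_config <- skipgram_config(seed = seed)
  corpus <- generate_walks(network, r = wp$r, l = wp$l, p = wp$p, q = wp$q,
                           seed = wp$seed, use_scores = wp$use_scores)
  emb <- suppressMessages(train_skipgram(corpus, sg_config))
  write_embedding_tsv(emb, file.path(outdir, "ppi_emb.tsv"))
  stage_log(outdir, "ppi_embedding",
            c(sprintf("nodes=%d edges=%d", length(network$nodes), n_edges(network)),
              sprintf("walks=%d walk_length=%d d=%d", length(corpus$walks),
                      wp$l, sg_config$dimension)))
  register_stage(outdir, inputs = inputs,
                 params = c(wp, unclass(sg_config)),
                 stage_name = "ppi_embedding")
  invisible(emb)
}
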
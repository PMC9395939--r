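# node2vec embedding of the similarity network: weighted biased random
# walks followed by skip-gram training with negative sampling.

#' Embed a similarity network with node2vec
#'
#' Runs weighted second-order random walks over the network (transition
#' probabilities proportional to edge weight times the return/in-out bias
#' given by `p` and `q`) and trains a skip-gram model with negative
#' sampling on the walk corpus. Defaults are the canonical node2vec
#' parameters: `p = q = 1`, 10 walks per node of length 80, window 10,
#' 5 negative samples, one epoch. Training is single-threaded and
#' deterministic for a fixed seed.
#'
#' @param network a [build_network()] result.
#' @param dim embedding dimension (128 by default).
#' @param seed RNG seed.
#' @param p,q node2vec return and in-out parameters.
#' @param walks_per_node,walk_length walk-corpus shape.
#' @param window,negative,epochs,alpha skip-gram training parameters
#'   (`alpha` is the initial learning rate).
#' @return a `dense_space` with provenance `"node2vec"`, one `dim`-length
#'   vector per network node.
#' @export
node2vec_embed <- function(network, dim = 128, seed = 1, p = 1, q = 1,
                           walks_per_node = 10, walk_length = 80,
                           window = 10, negative = 5, epochs = 1,
                           alpha = 0.025) {
  stopifnot(inherits(network, "similarity_network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) stop("empty network")
  ui <- match(network$edges$u, nodes)
  vi <- match(network$edges$v, nodes)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) { adj[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  for (e in seq_along(ui)) {
    adj[[ui[e]]] <- c(adj[[ui[e]]], vi[e] - 1L)
    wts[[ui[e]]] <- c(wts[[ui[e]]], network$edges$weight[e])
    adj[[vi[e]]] <- c(adj[[vi[e]]], ui[e] - 1L)
    wts[[vi[e]]] <- c(wts[[vi[e]]], network$edges$weight[e])
  }
  walks <- .node2vec_walks(adj, wts, p, q, as.integer(walks_per_node),
                           as.integer(walk_length), as.integer(seed))
  emb <- .sgns_train(walks, n, as.integer(dim), as.integer(window),
                     as.integer(negative), as.integer(epochs), alpha,
                     as.integer(seed))
  rownames(emb) <- nodes
  dense_space(emb, provenance = "node2vec")
}

#' One-nearest-neighbour label purity of a space
#'
#' Fraction of terms whose cosine-nearest other term carries the same
#' label; used to score ground-truth block recovery on synthetic data.
#'
#' @param space a space object.
#' @param labels named vector of labels (names = term ids).
#' @return purity in \[0,1\].
#' @export
nn_purity <- function(space, labels) {
  x <- as.matrix(space_matrix(space))
  terms <- space_terms(space)
  lab <- labels[terms]
  cs <- cosine_similarity(x)
  diag(cs) <- -Inf
  nn <- apply(cs, 1, which.max)
  mean(lab[nn] == lab)
}

#' Full hierarchy/association-to-embedding pipeline
#'
#' Convenience wrapper chaining [tfidf()], [reduce_svd()],
#' [empirical_null()], [build_network()] and [node2vec_embed()] with the
#' package defaults.
#'
#' @param corpus a `concept_corpus`.
#' @param dim node2vec dimension.
#' @param seed RNG seed used for the null sample and node2vec.
#' @param target_variance SVD explained-variance target.
#' @param min_df,max_df_frac TF-IDF document-frequency filters.
#' @param n_neighbors,weight_floor,forced_k network parameters.
#' @param n_pairs empirical-null sample size.
#' @return a `dense_space` with provenance `"node2vec"`.
#' @export
embed_concepts <- function(corpus, dim = 128, seed = 1, target_variance = 0.9,
                           min_df = 5, max_df_frac = 0.8, n_neighbors = 100,
                           weight_floor = 2, forced_k = 3, n_pairs = 100000) {
  sp <- tfidf(corpus, min_df = min_df, max_df_frac = max_df_frac)
  red <- reduce_svd(sp, target_variance = target_variance)
  null <- empirical_null(red, n_pairs = n_pairs, seed = seed)
  net <- build_network(red, null, n_neighbors = n_neighbors,
                       weight_floor = weight_floor, forced_k = forced_k)
  node2vec_embed(net, dim = dim, seed = seed)
}
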
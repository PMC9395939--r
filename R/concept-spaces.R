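# Concept-embedding learning: turn a hierarchy or association table into a
# corpus, weight it with TF-IDF, reduce with truncated SVD, build an
# empirical-null cosine similarity network and (see node2vec.R) embed it.

dense_space <- function(matrix, explained_variance = NA_real_,
                        provenance = c("svd", "node2vec", "composite",
                                       "raw")) {
  provenance <- match.arg(provenance)
  stopifnot(!is.null(rownames(matrix)))
  structure(list(terms = rownames(matrix), matrix = matrix,
                 explained_variance = explained_variance,
                 provenance = provenance),
            class = "dense_space")
}

#' @exportS3Method base::print
print.dense_space <- function(x, ...) {
  cat(sprintf("dense_space [%s]: %d terms x %d dims%s\n", x$provenance,
              nrow(x$matrix), ncol(x$matrix),
              if (!is.na(x$explained_variance))
                sprintf(" (explained variance %.3f)", x$explained_variance)
              else ""))
  invisible(x)
}

#' @exportS3Method base::print
print.sparse_space <- function(x, ...) {
  cat(sprintf("sparse_space: %d terms x %d vocabulary words\n",
              length(x$terms), length(x$vocab)))
  invisible(x)
}

# Matrix accessor working for both space flavours.
space_matrix <- function(space) {
  if (inherits(space, "dense_space")) space$matrix
  else if (inherits(space, "sparse_space")) space$matrix
  else if (is.matrix(space)) space
  else stop("not a space object")
}

space_terms <- function(space) {
  if (is.matrix(space)) rownames(space) else space$terms
}

#' Build a concept corpus from a term hierarchy
#'
#' Each tree number `c1.c2.....cn` contributes its `n` prefixes
#' `c1`, `c1.c2`, ..., as words; words from all of a term's tree numbers
#' are pooled with multiplicity, so sharing a deep path prefix makes two
#' terms' documents similar.
#'
#' @param hierarchy data.frame `term_id`, `tree_number` (one row per tree
#'   number).
#' @return object of class `concept_corpus`: named list of word multisets
#'   plus the source kind.
#' @export
corpus_from_hierarchy <- function(hierarchy) {
  stopifnot(all(c("term_id", "tree_number") %in% names(hierarchy)))
  prefixes <- function(tn) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
    vapply(seq_along(parts),
           function(k) paste(parts[seq_len(k)], collapse = "."), character(1))
  }
  docs <- lapply(split(hierarchy$tree_number, hierarchy$term_id),
                 function(tns) unlist(lapply(tns, prefixes), use.names = FALSE))
  missing <- !nzchar(names(docs)) | !lengths(docs)
  if (any(missing)) {
    warning(sprintf("%d terms without tree numbers excluded", sum(missing)))
    docs <- docs[!missing]
  }
  structure(list(documents = docs, source_kind = "hierarchy"),
            class = "concept_corpus")
}

#' Build a concept corpus from a bipartite association table
#'
#' A term's document is the multiset of its interacting partners.
#' Terms with no partners are simply absent (they become missing terms
#' downstream).
#'
#' @param associations data.frame `term_id`, `partner_id`.
#' @return a `concept_corpus`.
#' @export
corpus_from_associations <- function(associations) {
  stopifnot(all(c("term_id", "partner_id") %in% names(associations)))
  docs <- split(associations$partner_id, associations$term_id)
  docs <- docs[lengths(docs) > 0]
  structure(list(documents = docs, source_kind = "association"),
            class = "concept_corpus")
}

#' @exportS3Method base::print
print.concept_corpus <- function(x, ...) {
  cat(sprintf("concept_corpus [%s]: %d terms, %d distinct words\n",
              x$source_kind, length(x$documents),
              length(unique(unlist(x$documents, use.names = FALSE)))))
  invisible(x)
}

#' TF-IDF weighting of a concept corpus
#'
#' Words associated with fewer than `min_df` or more than
#' `max_df_frac * n_terms` of the terms (binary document frequency) are
#' removed before weighting. Weights are `tf * idf` with raw-count `tf`
#' and `idf = ln(n_terms / df) + 1`; no document-length normalisation.
#' Terms whose vector becomes all-zero are purged.
#'
#' @param corpus a `concept_corpus`.
#' @param min_df minimum document frequency (inclusive).
#' @param max_df_frac maximum document frequency as a fraction of terms
#'   (a word present in strictly more than this fraction is dropped).
#' @return object of class `sparse_space`: ordered `terms`, `vocab` and
#'   the sparse weight `matrix` (terms x vocab).
#' @export
tfidf <- function(corpus, min_df = 5, max_df_frac = 0.8) {
  stopifnot(inherits(corpus, "concept_corpus"))
  docs <- corpus$documents
  n <- length(docs)
  if (!n) stop("empty corpus")
  term_idx <- rep.int(seq_len(n), lengths(docs))
  word <- unlist(docs, use.names = FALSE)
  vocab_all <- sort(unique(word))
  word_idx <- match(word, vocab_all)
  counts <- Matrix::sparseMatrix(i = term_idx, j = word_idx, x = 1,
                                 dims = c(n, length(vocab_all)))
  df <- Matrix::colSums(counts > 0)
  keep <- df >= min_df & df <= max_df_frac * n
  if (!any(keep)) stop("all words removed by the document-frequency filters")
  counts <- counts[, keep, drop = FALSE]
  vocab <- vocab_all[keep]
  idf <- log(n / df[keep]) + 1
  w <- counts %*% Matrix::Diagonal(x = idf)
  nz <- Matrix::rowSums(w) > 0
  structure(list(terms = names(docs)[nz], vocab = vocab,
                 matrix = methods::as(w[nz, , drop = FALSE], "CsparseMatrix")),
            class = "sparse_space")
}

#' Truncated SVD dimensionality reduction
#'
#' Keeps the smallest number of components whose cumulative
#' explained-variance ratio (squared singular values over their total, on
#' the uncentred matrix) reaches `target_variance`, or exactly
#' `target_dim` components when given. When even the full rank explains
#' less than the target, the full rank is returned with a warning.
#'
#' @param space a `sparse_space`, `dense_space` or plain matrix with
#'   rownames.
#' @param target_variance fraction in (0,1); ignored when `target_dim` is
#'   given.
#' @param target_dim optional exact component count.
#' @return a `dense_space` with provenance `"svd"` and the achieved
#'   `explained_variance`.
#' @export
reduce_svd <- function(space, target_variance = 0.9, target_dim = NULL) {
  x <- as.matrix(space_matrix(space))
  terms <- space_terms(space) %||% rownames(x)
  s <- svd(x)
  tol <- max(dim(x)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  if (rank == 0) stop("zero matrix cannot be reduced")
  ev <- s$d^2 / sum(s$d^2)
  cum <- cumsum(ev)
  if (!is.null(target_dim)) {
    k <- check_count(target_dim, "target_dim")
    if (k > rank) {
      warning(sprintf("target_dim %d exceeds matrix rank %d; using rank",
                      k, rank))
      k <- rank
    }
  } else {
    check_fraction(target_variance, "target_variance", open_lo = TRUE,
                   open_hi = TRUE)
    hit <- which(cum[seq_len(rank)] >= target_variance)
    if (length(hit)) {
      k <- hit[1]
    } else {
      warning("full rank explains less than the target variance")
      k <- rank
    }
  }
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  rownames(scores) <- terms
  dense_space(scores, explained_variance = cum[k], provenance = "svd")
}

#' Empirical null distribution of cosine similarities
#'
#' Samples `n_pairs` pairs of distinct terms uniformly with replacement and
#' records their cosine similarities, sorted ascending. Zero-norm vectors
#' are excluded from the sampling pool with a warning.
#'
#' @param space a space object (>= 2 usable terms).
#' @param n_pairs number of sampled pairs.
#' @param seed RNG seed, stored with the sample.
#' @return object of class `empirical_null`: sorted `values`, `n_pairs`,
#'   `seed`.
#' @export
empirical_null <- function(space, n_pairs = 100000, seed = 1) {
  x <- as.matrix(space_matrix(space))
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    warning(sprintf("%d zero-norm vectors excluded from the null sample",
                    sum(nrm == 0)))
    x <- x[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  n <- nrow(x)
  if (n < 2) stop("need at least two non-zero terms")
  xn <- x / nrm
  vals <- with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- j + (j >= i)   # distinct indices, uniform over pairs
    rowSums(xn[i, , drop = FALSE] * xn[j, , drop = FALSE])
  })
  structure(list(values = sort(vals), n_pairs = as.integer(n_pairs),
                 seed = seed),
            class = "empirical_null")
}

#' Empirical p-value of a cosine similarity
#'
#' `p = (#{null >= s} + 1) / (n_pairs + 1)`; the add-one smoothing keeps
#' p-values strictly positive so that `-log10(p)` edge weights are finite.
#'
#' @param cos_sim numeric vector of cosine similarities.
#' @param null an `empirical_null`.
#' @return p-values in `(0, 1]`, non-increasing in `cos_sim`.
#' @export
pvalue <- function(cos_sim, null) {
  stopifnot(inherits(null, "empirical_null"))
  n <- length(null$values)
  n_lt <- findInterval(cos_sim, null$values, left.open = TRUE)
  (n - n_lt + 1) / (n + 1)
}

#' Build the empirical-null similarity network
#'
#' Candidate edges are the union, over terms, of each term's `n_neighbors`
#' highest-cosine partners (the query itself excluded; cosine ties broken
#' by ascending term id). Edge weight is `-log10(p-value)` under the
#' empirical null. Edges with weight `<= weight_floor` are pruned, except
#' that every term keeps its `forced_k` nearest neighbours regardless; an
#' edge survives if either endpoint demands it. The graph is undirected
#' with no self-edges.
#'
#' @param space the reduced space the null was computed on.
#' @param null an [empirical_null()] from the same space.
#' @param n_neighbors neighbourhood size.
#' @param weight_floor significance floor on `-log10(p)`.
#' @param forced_k nearest neighbours every term keeps.
#' @return object of class `similarity_network`: `nodes` and an `edges`
#'   data.frame (`u`, `v`, `weight`, `cosine`, `forced`).
#' @export
build_network <- function(space, null, n_neighbors = 100, weight_floor = 2,
                          forced_k = 3) {
  x <- as.matrix(space_matrix(space))
  terms <- space_terms(space)
  n <- nrow(x)
  if (n <= forced_k) stop("need more terms than forced_k")
  ord_terms <- order(terms)   # tie-break: ascending term id
  cs <- cosine_similarity(x)
  diag(cs) <- -Inf
  k_cand <- min(n_neighbors, n - 1L)
  edge_u <- integer(0); edge_v <- integer(0); forced_flag <- logical(0)
  for (i in seq_len(n)) {
    # order by descending cosine, ties by ascending term id
    o <- order(-cs[i, ], match(seq_len(n), ord_terms))
    nb <- o[seq_len(k_cand)]
    edge_u <- c(edge_u, rep.int(i, k_cand))
    edge_v <- c(edge_v, nb)
    forced_flag <- c(forced_flag, seq_len(k_cand) <= forced_k)
  }
  cos_e <- cs[cbind(edge_u, edge_v)]
  w <- -log10(pvalue(cos_e, null))
  keep <- w > weight_floor | forced_flag
  eu <- edge_u[keep]; ev <- edge_v[keep]
  wk <- w[keep]; ck <- cos_e[keep]; fk <- forced_flag[keep]
  a <- pmin(eu, ev); b <- pmax(eu, ev)
  key <- paste(a, b)
  first <- !duplicated(key)
  fa <- tapply(fk, key, any)
  edges <- data.frame(u = terms[a[first]], v = terms[b[first]],
                      weight = wk[first], cosine = ck[first],
                      forced = unname(fa[key[first]]),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = terms, edges = edges, null = null),
            class = "similarity_network")
}

#' @exportS3Method base::print
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a similarity network
#' @param network a `similarity_network`.
#' @return named integer vector over all nodes (isolated nodes get 0).
#' @export
network_degrees <- function(network) {
  tab <- table(factor(c(network$edges$u, network$edges$v),
                      levels = network$nodes))
  setNames(as.integer(tab), names(tab))
}

#' Write a similarity network as a weighted edge-list TSV
#' @param network a `similarity_network`.
#' @param path output file (`u  v  weight`).
#' @export
write_network <- function(network, path) {
  write_tsv_table(network$edges[, c("u", "v", "weight")], path)
}
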
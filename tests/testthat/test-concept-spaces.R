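test_that("hierarchy corpora contain all tree-number prefixes", {
  h <- data.frame(term_id = c("D1", "D2", "D2", "D3"),
                  tree_number = c("C06.552.195", "C06.552", "C25.100",
                                  "C06.100"))
  cc <- corpus_from_hierarchy(h)
  expect_setequal(cc$documents$D1, c("C06", "C06.552", "C06.552.195"))
  expect_length(cc$documents$D2, 4)          # pooled across both trees
  expect_true(all(c("C06") %in% cc$documents$D1) &&
                "C06" %in% cc$documents$D3)  # shared prefix shared as word
  expect_identical(cc$source_kind, "hierarchy")
})

test_that("association corpora are partner multisets", {
  a <- data.frame(term_id = c("A", "A", "A", "B"),
                  partner_id = c("g1", "g2", "g1", "g3"))
  cc <- corpus_from_associations(a)
  expect_identical(sort(cc$documents$A), c("g1", "g1", "g2"))
  expect_identical(cc$documents$B, "g3")
})

test_that("tfidf applies df filters before weighting and purges zero rows", {
  # 10-term corpus: "common" in 9 terms (> 80%), "rare" in 4 (< 5),
  # "mid" in 6 (kept). Terms containing only filtered words are purged.
  docs <- lapply(1:10, function(i) {
    d <- sprintf("w%d", i)                   # df = 1, always dropped
    if (i <= 6) d <- c(d, "mid")
    if (i <= 9) d <- c(d, "common")
    if (i <= 4) d <- c(d, "rare")
    d
  })
  names(docs) <- sprintf("T%02d", 1:10)
  corpus <- structure(list(documents = docs, source_kind = "association"),
                      class = "concept_corpus")
  sp <- tfidf(corpus, min_df = 5, max_df_frac = 0.8)
  expect_false("common" %in% sp$vocab)
  expect_false("rare" %in% sp$vocab)
  expect_identical(sp$vocab, "mid")
  expect_identical(sp$terms, sprintf("T%02d", 1:6))  # zero rows purged
  expect_error(tfidf(corpus, min_df = 50), "filters")
})

test_that("tfidf weights match the brute-force oracle exactly", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    docs <- lapply(seq_len(n), function(i)
      sample(sprintf("w%d", 1:12), sample(3:10, 1), replace = TRUE))
    names(docs) <- sprintf("T%02d", seq_len(n))
    corpus <- structure(list(documents = docs, source_kind = "association"),
                        class = "concept_corpus")
    oracle <- tfidf_oracle(docs, min_df = 2, max_df_frac = 0.8)
    if (ncol(oracle) == 0) next
    sp <- tfidf(corpus, min_df = 2, max_df_frac = 0.8)
    got <- as.matrix(sp$matrix)
    dimnames(got) <- list(sp$terms, sp$vocab)
    expect_equal(got[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
    expect_true(all(Matrix::rowSums(sp$matrix) > 0))
  }
})

test_that("reduce_svd picks the smallest k reaching the variance target", {
  # rank-1 limit case
  r1 <- outer(c(1, 2, 3), c(1, 0.5))
  rownames(r1) <- c("a", "b", "c")
  red1 <- reduce_svd(r1, 0.9)
  expect_identical(ncol(red1$matrix), 1L)
  expect_equal(red1$explained_variance, 1.0)

  # oracle from the full singular-value spectrum
  x <- random_space(50, 20, seed = 8)
  d2 <- svd(x)$d^2
  k_oracle <- which(cumsum(d2) / sum(d2) >= 0.9)[1]
  red <- reduce_svd(x, 0.9)
  expect_identical(ncol(red$matrix), as.integer(k_oracle))
  # scores reproduce the matrix geometry: pairwise inner products preserved
  expect_equal(tcrossprod(reduce_svd(x, target_dim = 20)$matrix),
               tcrossprod(x), tolerance = 1e-8)

  # monotonicity in the target
  expect_lte(ncol(reduce_svd(x, 0.9)$matrix), ncol(reduce_svd(x, 0.95)$matrix))
})

test_that("empirical null handles degenerate geometries", {
  same <- matrix(1, 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  null_same <- empirical_null(same, n_pairs = 500, seed = 1)
  expect_true(all(abs(null_same$values - 1) < 1e-12))

  ortho <- diag(4)
  rownames(ortho) <- paste0("t", 1:4)
  null_o <- empirical_null(ortho, n_pairs = 500, seed = 1)
  expect_true(all(abs(null_o$values) < 1e-12))

  expect_identical(empirical_null(same, n_pairs = 100, seed = 3),
                   empirical_null(same, n_pairs = 100, seed = 3))
  withzero <- rbind(same, t0 = c(0, 0, 0))
  expect_warning(empirical_null(withzero, n_pairs = 100, seed = 1),
                 "zero-norm")
})

test_that("pvalue implements add-one smoothing and is monotone", {
  null <- structure(list(values = sort(withr::with_seed(4, runif(1000, -1, 1))),
                         n_pairs = 1000L,
                         seed = 1L), class = "empirical_null")
  expect_equal(pvalue(2, null), 1 / 1001)       # above every null value
  expect_equal(pvalue(-2, null), 1.0)           # below every null value
  med <- median(null$values)
  expect_lt(abs(pvalue(med, null) - 0.5), 0.01)
  xs <- seq(-1, 1, length.out = 101)
  expect_true(all(diff(pvalue(xs, null)) <= 0))
})

test_that("build_network enforces the pruning and forced-neighbour rules", {
  x <- random_space(80, 10, seed = 12)
  null <- empirical_null(x, n_pairs = 20000, seed = 2)
  net <- build_network(x, null, n_neighbors = 30)
  deg <- network_degrees(net)
  expect_gte(min(deg), 3)
  expect_true(all(net$edges$u != net$edges$v))
  expect_false(any(duplicated(paste(pmin(net$edges$u, net$edges$v),
                                    pmax(net$edges$u, net$edges$v)))))
  expect_true(all(net$edges$weight[!net$edges$forced] > 2))
  # -log10 weight arithmetic: p = 1e-4 -> weight 4 > 2
  expect_equal(-log10(1e-4), 4)
  expect_error(build_network(x[1:3, ], null, forced_k = 3), "forced_k")
})

test_that("build_network is invariant to term ordering", {
  x <- random_space(40, 8, seed = 21)
  null <- empirical_null(x, n_pairs = 20000, seed = 5)
  perm <- withr::with_seed(3, sample(nrow(x)))
  canon <- function(net) {
    e <- data.frame(u = pmin(net$edges$u, net$edges$v),
                    v = pmax(net$edges$u, net$edges$v),
                    weight = net$edges$weight)
    e <- e[order(e$u, e$v), ]
    rownames(e) <- NULL
    e
  }
  n1 <- build_network(x, null, n_neighbors = 15)
  n2 <- build_network(x[perm, ], null, n_neighbors = 15)
  expect_equal(canon(n1), canon(n2))
})

test_that("node2vec produces deterministic block-aware embeddings", {
  # two 10-node cliques joined by one weak edge
  nodes <- sprintf("n%02d", 1:20)
  cl <- function(ix) t(combn(ix, 2))
  ed <- rbind(cl(1:10), cl(11:20))
  edges <- data.frame(u = nodes[ed[, 1]], v = nodes[ed[, 2]], weight = 5,
                      cosine = NA_real_, forced = FALSE)
  edges <- rbind(edges, data.frame(u = nodes[10], v = nodes[11],
                                   weight = 0.2, cosine = NA_real_,
                                   forced = TRUE))
  net <- structure(list(nodes = nodes, edges = edges, null = NULL),
                   class = "similarity_network")
  emb <- node2vec_embed(net, dim = 128, seed = 7)
  expect_identical(dim(emb$matrix), c(20L, 128L))

  cs <- dialogi:::cosine_similarity(emb$matrix)
  within <- c(cs[1:10, 1:10][upper.tri(diag(10))],
              cs[11:20, 11:20][upper.tri(diag(10))])
  between <- as.numeric(cs[1:10, 11:20])
  expect_gt(mean(within), mean(between))

  emb2 <- node2vec_embed(net, dim = 128, seed = 7)
  expect_identical(emb$matrix, emb2$matrix)
})
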
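# Independent oracles and small fixture builders shared across tests.

# Brute-force RBO: explicit term-by-term summation of the series
# (1-p) * sum_d p^(d-1) * A_d, with the extrapolated-agreement convention
# (prefix agreement held constant beyond the evaluated depth; the shorter
# list assumed to keep matching at its final rate). Independent of the
# closed form used by rbo().
rbo_series_oracle <- function(a, b, p) {
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  s <- la; l <- lb
  d_max <- max(l, ceiling(log(1e-18) / log(p)))
  total <- 0
  for (d in seq_len(d_max)) {
    if (d <= s) {
      x_d <- length(intersect(a[seq_len(d)], b[seq_len(d)]))
      agree <- x_d / d
    } else if (d <= l) {
      x_s <- length(intersect(a, b[seq_len(s)]))
      x_d <- length(intersect(a, b[seq_len(d)]))
      agree <- (x_d + (d - s) * x_s / s) / d
    } else {
      x_s <- length(intersect(a, b[seq_len(s)]))
      x_l <- length(intersect(a, b))
      agree <- (x_l - x_s) / l + x_s / s
    }
    total <- total + (1 - p) * p^(d - 1) * agree
  }
  total
}

# Spreadsheet-style TF-IDF oracle: dense loops, binary df, filter first.
tfidf_oracle <- function(docs, min_df, max_df_frac) {
  n <- length(docs)
  vocab <- sort(unique(unlist(docs)))
  counts <- sapply(vocab, function(w) vapply(docs, function(d)
    sum(d == w), numeric(1)))
  counts <- matrix(counts, nrow = n,
                   dimnames = list(names(docs), vocab))
  df <- colSums(counts > 0)
  keep <- df >= min_df & df <= max_df_frac * n
  counts <- counts[, keep, drop = FALSE]
  idf <- log(n / df[keep]) + 1
  w <- sweep(counts, 2, idf, "*")
  w[rowSums(w) > 0, , drop = FALSE]
}

# Confusion-matrix metrics oracle for evaluate().
metrics_oracle <- function(pred, labels, cls) {
  tp <- sum(pred == cls & labels == cls)
  fp <- sum(pred == cls & labels != cls)
  fn <- sum(pred != cls & labels == cls)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, f1 = f1)
}

# Random dense space fixture.
random_space <- function(n_terms, dim, seed, prefix = "D") {
  m <- dialogi:::with_seed(seed, matrix(rnorm(n_terms * dim), n_terms, dim))
  rownames(m) <- sprintf("%s%06d", prefix, seq_len(n_terms))
  m
}

# A small annotated corpus used by several files; built once per session.
shared_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_docs = 60, seed = 42, abstract_len = 60,
                          vocab_size = 500, n_disease_terms = 40,
                          n_chem_terms = 40, n_signal_concepts = 6)
      corp <- gen_documents(cfg)
      ann <- gen_annotations(corp)
      cache <<- list(corpus = corp, mentions = ann,
                     docs = annotate_corpus(corp$documents, ann))
    }
    cache
  }
})
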
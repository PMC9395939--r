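# Exploratory utilities over external feature vectors: normalisation ->
# PCA(15) -> 3D t-SNE, and cosine-ranked retrieval against a constructed
# concept query.

# Exact t-SNE (O(n^2)), sufficient for desk-scale corpora. Standard
# recipe: perplexity calibration by bisection on the Gaussian bandwidths,
# symmetrised P, early exaggeration, momentum gradient descent.
tsne_embed <- function(x, dims = 3, perplexity = 30, max_iter = 400,
                       seed = 1, eta = 200) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2
  p <- matrix(0, n, n)
  log_perp <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) sw <- .Machine$double.xmin
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - log_perp) < 1e-5) break
      if (h > log_perp) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  y <- with_seed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- matrix(0, n, dims)
  exaggeration <- 12
  momentum <- 0.5
  for (it in seq_len(max_iter)) {
    if (it == 51) exaggeration <- 1
    if (it == 251) momentum <- 0.8
    ysq <- rowSums(y^2)
    num <- 1 / (1 + outer(ysq, ysq, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (exaggeration * p - q) * num
    grad <- 4 * (diag(rowSums(l)) %*% y - l %*% y)
    inc <- momentum * inc - eta * grad
    y <- y + inc
    y <- scale(y, center = TRUE, scale = FALSE)
  }
  y
}

#' Project feature vectors to 3D with PCA + t-SNE
#'
#' Drops zero rows (unannotated documents), unit-normalises the remainder
#' so that euclidean and cosine distances become monotonically related,
#' keeps the first `pca_components` principal components and embeds them
#' in 3D with t-SNE on euclidean distances.
#'
#' @param feature_matrix documents x dims matrix (doc ids as rownames).
#' @param labels optional labels carried into the result.
#' @param seed RNG seed (single-threaded, deterministic).
#' @param perplexity t-SNE perplexity; capped at `(n-1)/3` for small
#'   inputs.
#' @param pca_components retained principal components (15).
#' @param max_iter t-SNE iterations.
#' @return object of class `projection`: `coordinates` (n_nonzero x 3),
#'   `doc_ids`, `labels`, `dropped` (ids of zero rows).
#' @export
project <- function(feature_matrix, labels = NULL, seed = 1, perplexity = 30,
                    pca_components = 15, max_iter = 400) {
  nrm <- sqrt(rowSums(feature_matrix^2))
  keep <- nrm > 0
  if (sum(keep) < 16) {
    stop("fewer than 16 non-zero feature vectors; reduce pca_components ",
         "or provide more annotated documents")
  }
  x <- feature_matrix[keep, , drop = FALSE] / nrm[keep]
  k <- min(pca_components, ncol(x), nrow(x) - 1)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  y <- tsne_embed(pc, dims = 3, perplexity = perplexity, max_iter = max_iter,
                  seed = seed)
  rownames(y) <- rownames(feature_matrix)[keep]
  structure(list(coordinates = y,
                 doc_ids = rownames(feature_matrix)[keep],
                 labels = if (!is.null(labels)) labels[keep] else NULL,
                 dropped = rownames(feature_matrix)[!keep],
                 pca_components = k),
            class = "projection")
}

#' @exportS3Method base::print
print.projection <- function(x, ...) {
  cat(sprintf("projection: %d documents in 3D (%d zero rows dropped)\n",
              nrow(x$coordinates), length(x$dropped)))
  invisible(x)
}

#' Mean silhouette of labels in a projection
#'
#' Simple euclidean silhouette over the 3D coordinates; positive values
#' indicate that same-label documents sit closer together than
#' cross-label ones.
#' @param projection a [project()] result with labels.
#' @return mean silhouette width in \[-1,1\].
#' @export
projection_silhouette <- function(projection) {
  y <- projection$coordinates
  lab <- projection$labels
  stopifnot(!is.null(lab))
  d <- as.matrix(stats::dist(y))
  ulab <- unique(lab)
  s <- vapply(seq_len(nrow(y)), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(nrow(y)) != i])
    b <- min(vapply(ulab[ulab != lab[i]], function(g)
      mean(d[i, lab == g]), numeric(1)))
    if (is.nan(a)) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Build a query feature vector exactly like a document's: per-category
# weighted average, unit-normalised, disease part first.
query_vector <- function(concepts, disease_space, chemical_space) {
  stopifnot(is.data.frame(concepts),
            all(c("concept_id", "category", "weight") %in% names(concepts)))
  missing <- !(concepts$concept_id %in% c(space_terms(disease_space),
                                          space_terms(chemical_space)))
  if (all(missing)) stop("all query concepts are missing from the spaces")
  if (any(missing)) {
    warning("query concepts missing from the spaces: ",
            paste(concepts$concept_id[missing], collapse = ", "))
  }
  part <- function(cat, space) {
    sub <- concepts[concepts$category == cat, , drop = FALSE]
    w <- setNames(sub$weight, sub$concept_id)
    if (length(w)) w <- w / sum(w)
    category_vector(w, space)
  }
  c(part("disease", disease_space), part("chemical", chemical_space))
}

#' Rank documents against a concept query
#'
#' The query is a set of weighted disease/chemical concepts; its feature
#' vector is built exactly like a document's (frequency-weighted average
#' per category, unit-normalised, concatenated disease-first) and
#' documents are ranked by cosine similarity. Because each half is
#' normalised separately, a disease-only query is unaffected by the
#' documents' chemical parts.
#'
#' @param concepts data.frame `concept_id`, `category`
#'   ("disease"/"chemical"), `weight`.
#' @param disease_space,chemical_space composed spaces.
#' @param feature_matrix documents x dims feature matrix.
#' @param top number of hits to return (default all).
#' @return object of class `query_result`: data.frame `doc_id`,
#'   `similarity` sorted descending, plus the query vector.
#' @export
query <- function(concepts, disease_space, chemical_space, feature_matrix,
                  top = nrow(feature_matrix)) {
  qv <- query_vector(concepts, disease_space, chemical_space)
  if (length(qv) != ncol(feature_matrix)) {
    stop("feature matrix dimension does not match the composed spaces")
  }
  qn <- sqrt(sum(qv^2))
  dn <- sqrt(rowSums(feature_matrix^2))
  sim <- as.numeric(feature_matrix %*% qv)
  nz <- dn > 0 & qn > 0
  sim[nz] <- sim[nz] / (dn[nz] * qn)
  sim[!nz] <- 0
  o <- order(-sim)
  o <- o[seq_len(min(top, length(o)))]
  structure(list(
    ranking = data.frame(doc_id = rownames(feature_matrix)[o],
                         similarity = sim[o], stringsAsFactors = FALSE),
    query = qv, concepts = concepts
  ), class = "query_result")
}

#' @exportS3Method base::print
print.query_result <- function(x, ...) {
  cat(sprintf("query_result: top hit %s (cosine %.3f) of %d documents\n",
              x$ranking$doc_id[1], x$ranking$similarity[1], nrow(x$ranking)))
  invisible(x)
}

#' Explain a retrieval hit concept-by-concept
#'
#' Cosine similarity between each query concept and each same-category
#' concept mentioned in the document, ordered by decreasing in-text
#' frequency of the document concept.
#'
#' @param concepts query concepts (as in [query()]).
#' @param doc an `annotated_document`.
#' @param disease_space,chemical_space composed spaces.
#' @return data.frame `query_concept`, `doc_concept`, `category`,
#'   `doc_freq`, `similarity`.
#' @export
explain_hit <- function(concepts, doc, disease_space, chemical_space) {
  rows <- list()
  for (cat in c("disease", "chemical")) {
    space <- if (cat == "disease") disease_space else chemical_space
    qc <- concepts$concept_id[concepts$category == cat]
    freqs <- doc$rel_freq[[cat]]
    dc <- names(freqs)[order(-freqs)]
    if (!length(qc) || !length(dc)) next
    m <- as.matrix(space_matrix(space))
    for (q in qc) {
      for (d in dc) {
        sim <- if (q %in% rownames(m) && d %in% rownames(m)) {
          as.numeric(cosine_similarity(m[q, , drop = FALSE],
                                       m[d, , drop = FALSE]))
        } else {
          NA_real_
        }
        rows[[length(rows) + 1L]] <-
          data.frame(query_concept = q, doc_concept = d, category = cat,
                     doc_freq = unname(freqs[d]), similarity = sim,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_concept = character(), doc_concept = character(),
               category = character(), doc_freq = numeric(),
               similarity = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
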
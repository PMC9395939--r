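# Agreement between two concept spaces: averaged rank-biased overlap of
# cosine-nearest-neighbour lists and CCA-based Pearson correlation.

#' Extrapolated rank-biased overlap of two ranked lists
#'
#' Top-weighted similarity of two finite ranked lists without duplicates.
#' The persistence parameter `p` is the probability of looking one rank
#' deeper; smaller `p` makes the measure more top-weighted. This is the
#' extrapolated point estimate: agreement beyond the evaluated depth is
#' assumed to stay at its value at that depth, so identical lists score 1
#' and disjoint lists score 0.
#'
#' @param a,b character (or atomic) vectors, no duplicates within a list.
#' @param p persistence in (0,1).
#' @return score in \[0,1\].
#' @export
rbo <- function(a, b, p = 0.7) {
  check_fraction(p, "p", open_lo = TRUE, open_hi = TRUE)
  if (anyDuplicated(a) || anyDuplicated(b)) {
    stop("ranked lists must not contain duplicate items")
  }
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  s <- la; l <- lb
  # X_d: size of the intersection of the depth-d prefixes (the shorter
  # list stops growing at its full length)
  x <- numeric(l)
  seen_a <- character(0); seen_b <- character(0)
  overlap <- 0
  for (d in seq_len(l)) {
    if (d <= s) {
      ai <- a[d]; bi <- b[d]
      if (ai == bi) {
        overlap <- overlap + 1
      } else {
        if (ai %in% seen_b) overlap <- overlap + 1
        if (bi %in% seen_a) overlap <- overlap + 1
      }
      seen_a <- c(seen_a, ai); seen_b <- c(seen_b, bi)
    } else {
      if (b[d] %in% a) overlap <- overlap + 1
    }
    x[d] <- overlap
  }
  d_seq <- seq_len(l)
  pd <- p^d_seq
  total <- sum(x / d_seq * pd)
  if (l > s) {
    d_tail <- (s + 1):l
    total <- total + sum(x[s] * (d_tail - s) / (s * d_tail) * p^d_tail)
  }
  ((1 - p) / p) * total + ((x[l] - x[s]) / l + x[s] / s) * p^l
}

# Cosine-ranked neighbour lists for every row, query excluded, ties broken
# by ascending term id. Returns a list of character vectors.
neighbour_lists <- function(space, depth) {
  x <- as.matrix(space_matrix(space))
  terms <- space_terms(space)
  cs <- cosine_similarity(x)
  diag(cs) <- -Inf
  tie_rank <- match(seq_along(terms), order(terms))
  lapply(seq_along(terms), function(i) {
    o <- order(-cs[i, ], tie_rank)
    terms[o[seq_len(min(depth, length(terms) - 1L))]]
  })
}

#' Averaged RBO between two concept spaces
#'
#' Identifies the terms common to both spaces, builds each common term's
#' cosine-ranked neighbour list restricted to the common terms in each
#' space, and averages the per-term RBO scores.
#'
#' @param space_a,space_b space objects.
#' @param n_neighbors neighbour-list depth.
#' @param p RBO persistence.
#' @return mean RBO over common terms.
#' @export
rbo_between_spaces <- function(space_a, space_b, n_neighbors = 100, p = 0.7) {
  common <- intersect(space_terms(space_a), space_terms(space_b))
  if (length(common) < 2) stop("need at least two common terms")
  ma <- as.matrix(space_matrix(space_a))[common, , drop = FALSE]
  mb <- as.matrix(space_matrix(space_b))[common, , drop = FALSE]
  la <- neighbour_lists(dense_space(ma, provenance = "raw"), n_neighbors)
  lb <- neighbour_lists(dense_space(mb, provenance = "raw"), n_neighbors)
  mean(vapply(seq_along(common), function(i) rbo(la[[i]], lb[[i]], p),
              numeric(1)))
}

# Inverse square root of a symmetric PSD matrix, ridge-stabilised.
inv_sqrt_sym <- function(s, ridge) {
  e <- eigen(s + ridge * diag(nrow(s)), symmetric = TRUE)
  keep <- e$values > .Machine$double.eps * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

#' CCA-based Pearson correlation between two spaces
#'
#' Fits (ridge-regularised) canonical correlation analysis on the rows of
#' the two spaces restricted to their common terms, computes the in-sample
#' Pearson correlation of each of the first `n_components` canonical
#' variable pairs, and returns their mean. The small ridge keeps the fit
#' defined when there are fewer terms than dimensions (a warning is
#' emitted in that overfit regime).
#'
#' @param space_a,space_b space objects.
#' @param n_components canonical pairs to average (3 by default).
#' @param ridge regularisation added to both covariance blocks.
#' @return mean Pearson correlation in \[-1,1\].
#' @export
cca_pearson <- function(space_a, space_b, n_components = 3, ridge = 1e-3) {
  common <- intersect(space_terms(space_a), space_terms(space_b))
  if (length(common) < 2) stop("need at least two common terms")
  x <- as.matrix(space_matrix(space_a))[common, , drop = FALSE]
  y <- as.matrix(space_matrix(space_b))[common, , drop = FALSE]
  n <- length(common)
  if (n <= max(ncol(x), ncol(y))) {
    warning("fewer common terms than dimensions: CCA is in the overfit ",
            "regime; ridge regularisation applied")
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  sxx <- crossprod(x) / n
  syy <- crossprod(y) / n
  sxy <- crossprod(x, y) / n
  wx <- inv_sqrt_sym(sxx, ridge)
  wy <- inv_sqrt_sym(syy, ridge)
  sv <- svd(wx %*% sxy %*% wy)
  k <- min(n_components, length(sv$d))
  u <- x %*% (wx %*% sv$u[, seq_len(k), drop = FALSE])
  v <- y %*% (wy %*% sv$v[, seq_len(k), drop = FALSE])
  cors <- vapply(seq_len(k), function(i) {
    if (sd(u[, i]) == 0 || sd(v[, i]) == 0) return(0)
    cor(u[, i], v[, i])
  }, numeric(1))
  mean(cors)
}

#' Full comparison of two concept spaces
#'
#' @inheritParams rbo_between_spaces
#' @param n_components canonical pairs for [cca_pearson()].
#' @return object of class `space_comparison` with `rbo_score`,
#'   `cca_pearson`, `n_common_terms` and `p`.
#' @export
compare_spaces <- function(space_a, space_b, n_neighbors = 100, p = 0.7,
                           n_components = 3) {
  common <- intersect(space_terms(space_a), space_terms(space_b))
  if (length(common) < 2) stop("need at least two common terms")
  structure(list(
    rbo_score = rbo_between_spaces(space_a, space_b, n_neighbors, p),
    cca_pearson = cca_pearson(space_a, space_b, n_components),
    n_common_terms = length(common),
    p = p
  ), class = "space_comparison")
}

#' @exportS3Method base::print
print.space_comparison <- function(x, ...) {
  cat(sprintf("space_comparison: RBO %.4f, CCA Pearson %.4f (%d common terms, p = %.2f)\n",
              x$rbo_score, x$cca_pearson, x$n_common_terms, x$p))
  invisible(x)
}
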
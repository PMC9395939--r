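# Composite concept spaces and per-document external feature vectors:
# frequency-weighted averages of disease and chemical embeddings,
# unit-normalised per category and concatenated disease-first.

#' Compose member spaces into a single concept space
#'
#' Member spaces are aligned on the union of their term universes (missing
#' terms become zero rows; vectors are deliberately not centred or scaled),
#' concatenated column-wise within each group, each group is reduced by
#' truncated SVD to its target, and the reduced groups are concatenated.
#' A target below 1 is interpreted as an explained-variance fraction, a
#' target of 1 or more as an exact component count.
#'
#' @param member_groups list of groups; each group is a list of space
#'   objects (or a single space).
#' @param targets numeric vector/list parallel to `member_groups`.
#' @return a `dense_space` with provenance `"composite"`.
#' @export
compose_space <- function(member_groups, targets) {
  stopifnot(length(member_groups) == length(targets))
  member_groups <- lapply(member_groups, function(g)
    if (inherits(g, c("dense_space", "sparse_space")) || is.matrix(g))
      list(g) else g)
  all_members <- unlist(member_groups, recursive = FALSE)
  term_sets <- lapply(all_members, space_terms)
  if (length(Reduce(intersect, term_sets)) == 0) {
    stop("member spaces have disjoint term universes")
  }
  universe <- sort(unique(unlist(term_sets)))
  aligned <- function(space) {
    m <- as.matrix(space_matrix(space))
    out <- matrix(0, nrow = length(universe), ncol = ncol(m),
                  dimnames = list(universe, NULL))
    out[rownames(m), ] <- m
    out
  }
  reduced <- lapply(seq_along(member_groups), function(gi) {
    g <- do.call(cbind, lapply(member_groups[[gi]], aligned))
    rownames(g) <- universe
    tgt <- targets[[gi]]
    red <- if (tgt < 1) {
      reduce_svd(g, target_variance = tgt)
    } else {
      reduce_svd(g, target_dim = as.integer(tgt))
    }
    red$matrix
  })
  out <- do.call(cbind, reduced)
  rownames(out) <- universe
  colnames(out) <- NULL
  dense_space(out, provenance = "composite")
}

#' SVD targets used for the reference composite spaces
#'
#' The reference configuration reduces the concatenated association-based
#' disease spaces to 103 dimensions and the hierarchy-based disease space
#' to 47 (150 total, ~90% variance each), and the concatenated chemical
#' signature spaces to 265 plus 35 hierarchy dimensions (300 total, ~80%
#' variance each). Classification thresholds: 0.5 baseline, 0.7 extended.
#'
#' @return a named list of targets and thresholds.
#' @export
paper_profile <- function() {
  list(disease = c(association = 103, hierarchy = 47),
       chemical = c(signatures = 265, hierarchy = 35),
       thresholds = c(baseline = 0.5, extended = 0.7))
}

# Weighted average of concept vectors for one category; missing terms
# contribute zero and their weight mass is not redistributed.
category_vector <- function(freqs, space) {
  m <- space_matrix(space)
  v <- numeric(ncol(m))
  if (length(freqs)) {
    hit <- names(freqs)[names(freqs) %in% rownames(m)]
    if (length(hit)) {
      v <- as.numeric(freqs[hit] %*% as.matrix(m[hit, , drop = FALSE]))
    }
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' External feature vector of one annotated document
#'
#' Per category, the relative-frequency-weighted average of the mentioned
#' concepts' embeddings (missing concepts count as zero vectors), each
#' normalised to unit length unless it is exactly zero; the disease part
#' comes first. The coverage flags record annotation presence, not vector
#' presence: a document whose every mentioned term is missing from the
#' space keeps a `TRUE` flag with a zero part.
#'
#' @param doc an `annotated_document`.
#' @param disease_space,chemical_space composed `dense_space`s.
#' @return numeric vector of length `disease_dim + chemical_dim` with
#'   attributes `has_disease`, `has_chemical` and `doc_id`.
#' @export
text_vector <- function(doc, disease_space, chemical_space) {
  stopifnot(inherits(doc, "annotated_document"))
  d <- category_vector(doc$rel_freq$disease, disease_space)
  c_ <- category_vector(doc$rel_freq$chemical, chemical_space)
  structure(c(d, c_),
            has_disease = length(doc$rel_freq$disease) > 0,
            has_chemical = length(doc$rel_freq$chemical) > 0,
            doc_id = doc$doc_id)
}

#' Featurize a corpus of annotated documents
#'
#' @param docs list of `annotated_document`s (unique ids).
#' @param disease_space,chemical_space composed `dense_space`s.
#' @return list with `features` (docs x dims matrix, doc ids as rownames),
#'   `flags` (logical matrix `has_disease`, `has_chemical`) and `coverage`
#'   (per-class fraction of documents with at least one disease / chemical
#'   mention; class `NA` pools everything when labels are absent).
#' @export
batch_featurize <- function(docs, disease_space, chemical_space) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate document ids")
  vecs <- lapply(docs, text_vector, disease_space = disease_space,
                 chemical_space = chemical_space)
  features <- do.call(rbind, lapply(vecs, as.numeric))
  rownames(features) <- ids
  flags <- cbind(has_disease = vapply(vecs, attr, logical(1), "has_disease"),
                 has_chemical = vapply(vecs, attr, logical(1), "has_chemical"))
  rownames(flags) <- ids
  labels <- vapply(docs, function(d) as.integer(d$label %||% NA_integer_),
                   integer(1))
  coverage <- do.call(rbind, lapply(
    split(seq_along(docs), factor(labels, exclude = NULL)), function(ix)
    data.frame(class = labels[ix[1]],
               disease = mean(flags[ix, "has_disease"]),
               chemical = mean(flags[ix, "has_chemical"]),
               n = length(ix))))
  rownames(coverage) <- NULL
  list(features = features, flags = flags, coverage = coverage)
}
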
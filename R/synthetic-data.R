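#' Configuration for the synthetic corpus generator
#'
#' Builds and validates the configuration object consumed by
#' [gen_documents()] and [gen_annotations()]. The generator emulates a
#' two-class literature-triage corpus (e.g. DILI-positive vs negative
#' abstracts) with planted lexical and concept signal: class-discriminative
#' tokens appear with probability `signal_strength` in documents of their
#' own class and `noise_rate` in the other class; class-discriminative
#' disease/chemical concepts behave the same way under `concept_signal`.
#' Discriminative concepts of the two classes are drawn from disjoint
#' ground-truth blocks so that concept-embedding features carry class
#' signal once the blocks are recovered.
#'
#' @param n_docs number of documents.
#' @param class_balance fraction of positive documents, in (0,1).
#' @param vocab_size size of the background vocabulary.
#' @param n_disease_terms,n_chem_terms number of synthetic MeSH-style
#'   disease and chemical descriptors.
#' @param n_blocks number of ground-truth concept clusters.
#' @param signal_strength probability that a class-discriminative lexical
#'   token is emitted in a document of its class, in \[0,1\].
#' @param concept_signal same, for class-discriminative concepts; defaults
#'   to `signal_strength`.
#' @param noise_rate emission probability of a discriminative token/concept
#'   in the opposite class, in \[0,1\].
#' @param fraction_unannotated fraction of documents that receive zero
#'   concept annotations (exercises the zero-feature fallback path).
#' @param n_signal_tokens discriminative lexical tokens per class.
#' @param n_signal_concepts discriminative concepts per class and category.
#' @param abstract_len mean abstract length in background tokens.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_docs = 2000, class_balance = 0.5,
                         vocab_size = 5000,
                         n_disease_terms = 100, n_chem_terms = 100,
                         n_blocks = 4,
                         signal_strength = 0.8, concept_signal = signal_strength,
                         noise_rate = 0.05, fraction_unannotated = 0.2,
                         n_signal_tokens = 12, n_signal_concepts = 8,
                         abstract_len = 150, seed = 1) {
  cfg <- list(
    n_docs = check_count(n_docs, "n_docs"),
    class_balance = check_fraction(class_balance, "class_balance",
                                   open_lo = TRUE, open_hi = TRUE),
    vocab_size = check_count(vocab_size, "vocab_size"),
    n_disease_terms = check_count(n_disease_terms, "n_disease_terms"),
    n_chem_terms = check_count(n_chem_terms, "n_chem_terms"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    signal_strength = check_fraction(signal_strength, "signal_strength"),
    concept_signal = check_fraction(concept_signal, "concept_signal"),
    noise_rate = check_fraction(noise_rate, "noise_rate"),
    fraction_unannotated = check_fraction(fraction_unannotated,
                                          "fraction_unannotated"),
    n_signal_tokens = check_count(n_signal_tokens, "n_signal_tokens"),
    n_signal_concepts = check_count(n_signal_concepts, "n_signal_concepts"),
    abstract_len = check_count(abstract_len, "abstract_len", min = 30L),
    seed = check_count(seed, "seed", min = 0L)
  )
  n_terms <- min(cfg$n_disease_terms, cfg$n_chem_terms)
  if (2L * cfg$n_signal_concepts > n_terms) {
    stop_config("n_signal_concepts too large for the number of terms")
  }
  structure(cfg, class = "synth_config")
}

# Function words mixed into the background text so the stopword/POS filter
# has something to do.
synth_function_words <- c("the", "and", "was", "were", "with", "for", "are",
                          "this", "that", "from", "have", "been", "not")

# Synthetic descriptor table: disease and chemical ids share the D-prefixed
# MeSH-style syntax and are distinguished by category only.
synth_concept_table <- function(cfg) {
  nd <- cfg$n_disease_terms
  nc <- cfg$n_chem_terms
  ids <- sprintf("D%06d", seq_len(nd + nc))
  category <- rep(c("disease", "chemical"), c(nd, nc))
  surface <- c(sprintf("disterm%04d", seq_len(nd)),
               sprintf("chmterm%04d", seq_len(nc)))
  block <- c(rep_len(seq_len(cfg$n_blocks), nd),
             rep_len(seq_len(cfg$n_blocks), nc))
  data.frame(concept_id = ids, category = category, surface = surface,
             block = block, stringsAsFactors = FALSE)
}

#' Generate a synthetic two-class document corpus
#'
#' Titles and abstracts are drawn from a two-level token model: a shared
#' Zipf-weighted background vocabulary (plus function words) and
#' class-specific discriminative tokens/concept surfaces planted per the
#' configuration. A manifest of the planted discriminative items is
#' attached so tests can measure recovery.
#'
#' @param config a [synth_config()].
#' @param manifest optional manifest from a previous corpus; when given,
#'   the same discriminative tokens and concepts are planted (used to
#'   generate distribution-shifted evaluation sets that share the training
#'   corpus's ground truth while e.g. degrading the lexical signal).
#' @return an object of class `synth_corpus`: a list with `documents`
#'   (data.frame `id`, `title`, `abstract`, `label`), `concepts` (the
#'   synthetic descriptor table), `manifest` (planted discriminative
#'   tokens/concepts with their class), and `config`.
#' @export
gen_documents <- function(config, manifest = NULL) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    vocab <- sprintf("w%05d", seq_len(cfg$vocab_size))
    zipf <- 1 / (seq_len(cfg$vocab_size) + 2.7)
    zipf <- zipf / sum(zipf)

    pos_tokens <- sprintf("pstok%02d", seq_len(cfg$n_signal_tokens))
    neg_tokens <- sprintf("ngtok%02d", seq_len(cfg$n_signal_tokens))

    concepts <- synth_concept_table(cfg)
    pos_blocks <- seq_len(max(1L, cfg$n_blocks %/% 2L))
    sig <- lapply(c(disease = "disease", chemical = "chemical"), function(cat) {
      pool_pos <- concepts$concept_id[concepts$category == cat &
                                        concepts$block %in% pos_blocks]
      pool_neg <- concepts$concept_id[concepts$category == cat &
                                        !(concepts$block %in% pos_blocks)]
      list(pos = sample(pool_pos, min(cfg$n_signal_concepts, length(pool_pos))),
           neg = sample(pool_neg, min(cfg$n_signal_concepts, length(pool_neg))))
    })
    if (is.null(manifest)) {
      sig_concepts_pos <- c(sig$disease$pos, sig$chemical$pos)
      sig_concepts_neg <- c(sig$disease$neg, sig$chemical$neg)
    } else {
      mc <- manifest[manifest$kind == "concept", , drop = FALSE]
      sig_concepts_pos <- mc$id[mc$class == 1L]
      sig_concepts_neg <- mc$id[mc$class == 0L]
      if (!all(c(sig_concepts_pos, sig_concepts_neg) %in%
                 concepts$concept_id)) {
        stop_config("manifest concepts are outside this config's term set")
      }
    }
    background_concepts <- setdiff(concepts$concept_id,
                                   c(sig_concepts_pos, sig_concepts_neg))
    surface_of <- setNames(concepts$surface, concepts$concept_id)

    n_pos <- round(cfg$class_balance * cfg$n_docs)
    label <- sample(rep(c(1L, 0L), c(n_pos, cfg$n_docs - n_pos)))
    n_unann <- round(cfg$fraction_unannotated * cfg$n_docs)
    unannotated <- seq_len(cfg$n_docs) %in% sample(cfg$n_docs, n_unann)

    draw_background <- function(n) {
      fw <- runif(n) < 0.15
      out <- character(n)
      out[fw] <- sample(synth_function_words, sum(fw), replace = TRUE)
      out[!fw] <- sample(vocab, sum(!fw), replace = TRUE, prob = zipf)
      out
    }

    titles <- character(cfg$n_docs)
    abstracts <- character(cfg$n_docs)
    for (i in seq_len(cfg$n_docs)) {
      own_tok <- if (label[i] == 1L) pos_tokens else neg_tokens
      oth_tok <- if (label[i] == 1L) neg_tokens else pos_tokens
      planted <- c(own_tok[runif(length(own_tok)) < cfg$signal_strength],
                   oth_tok[runif(length(oth_tok)) < cfg$noise_rate])

      if (!unannotated[i]) {
        own_cpt <- if (label[i] == 1L) sig_concepts_pos else sig_concepts_neg
        oth_cpt <- if (label[i] == 1L) sig_concepts_neg else sig_concepts_pos
        emitted <- c(own_cpt[runif(length(own_cpt)) < cfg$concept_signal],
                     oth_cpt[runif(length(oth_cpt)) < cfg$noise_rate],
                     sample(background_concepts,
                            min(1L + stats::rpois(1, 1), length(background_concepts))))
        emitted <- unique(emitted)
        reps <- 1L + stats::rbinom(length(emitted), 2L, 0.3)
        planted <- c(planted, rep(surface_of[emitted], reps))
      }

      body <- sample(c(draw_background(cfg$abstract_len), planted))
      titles[i] <- paste(draw_background(sample(3:8, 1)), collapse = " ")
      abstracts[i] <- paste(body, collapse = " ")
    }

    documents <- data.frame(
      id = sprintf("%d", 10000L + seq_len(cfg$n_docs)),
      title = titles, abstract = abstracts, label = label,
      stringsAsFactors = FALSE
    )
    manifest <- rbind(
      data.frame(kind = "token", id = pos_tokens, class = 1L,
                 category = NA_character_, stringsAsFactors = FALSE),
      data.frame(kind = "token", id = neg_tokens, class = 0L,
                 category = NA_character_, stringsAsFactors = FALSE),
      data.frame(kind = "concept", id = sig_concepts_pos, class = 1L,
                 category = concepts$category[match(sig_concepts_pos,
                                                    concepts$concept_id)],
                 stringsAsFactors = FALSE),
      data.frame(kind = "concept", id = sig_concepts_neg, class = 0L,
                 category = concepts$category[match(sig_concepts_neg,
                                                    concepts$concept_id)],
                 stringsAsFactors = FALSE)
    )
    structure(list(documents = documents, concepts = concepts,
                   manifest = manifest, unannotated = documents$id[unannotated],
                   config = cfg),
              class = "synth_corpus")
  })
}

#' @exportS3Method base::print
print.synth_corpus <- function(x, ...) {
  cat(sprintf("synth_corpus: %d documents (%d positive), %d concepts, seed %d\n",
              nrow(x$documents), sum(x$documents$label == 1L),
              nrow(x$concepts), x$config$seed))
  invisible(x)
}

# Raw text under the single offset convention: title + one space + abstract.
raw_text <- function(title, abstract) paste(title, abstract)

#' Derive concept annotations for a synthetic corpus
#'
#' Scans each document's raw text (title + single space + abstract) for the
#' concept surfaces planted by [gen_documents()] and emits exact 0-based,
#' half-open character offsets, PubTator style.
#'
#' @param corpus a `synth_corpus`.
#' @return data.frame with columns `doc_id`, `start`, `end`, `text`,
#'   `type` ("Chemical"/"Disease") and `concept_id`.
#' @export
gen_annotations <- function(corpus) {
  stopifnot(inherits(corpus, "synth_corpus"))
  surf <- corpus$concepts
  id_of <- setNames(surf$concept_id, surf$surface)
  type_of <- setNames(ifelse(surf$category == "chemical", "Chemical", "Disease"),
                      surf$surface)
  out <- vector("list", nrow(corpus$documents))
  for (i in seq_len(nrow(corpus$documents))) {
    txt <- raw_text(corpus$documents$title[i], corpus$documents$abstract[i])
    toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
    ends <- cumsum(nchar(toks) + 1L) - 1L   # position after token
    starts <- ends - nchar(toks)
    hit <- toks %in% surf$surface
    if (!any(hit)) next
    if (any(ends[hit] > nchar(txt))) {
      stop("internal error: annotation offset outside document ",
           corpus$documents$id[i])
    }
    out[[i]] <- data.frame(
      doc_id = corpus$documents$id[i],
      start = starts[hit], end = ends[hit], text = toks[hit],
      type = unname(type_of[toks[hit]]),
      concept_id = unname(id_of[toks[hit]]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(doc_id = character(), start = integer(), end = integer(),
                      text = character(), type = character(),
                      concept_id = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Generate a random MeSH-style term hierarchy
#'
#' Every term receives one or more dot-delimited tree numbers rooted at a
#' block-specific subcategory code, so ground-truth block co-membership
#' correlates with shared path prefixes.
#'
#' @param n_terms number of terms.
#' @param depth maximum number of dot-separated components per tree number
#'   (must be >= 2).
#' @param branching children per internal node.
#' @param n_blocks number of ground-truth blocks.
#' @param seed RNG seed.
#' @param term_ids optional explicit term ids (default `D000001`, ...).
#' @param blocks optional explicit block assignment per term.
#' @param multi_prob probability that a term carries a second tree number.
#' @return data.frame (`term_id`, `tree_number`), one row per tree number,
#'   with the block assignment in `attr(, "blocks")`.
#' @export
gen_hierarchy <- function(n_terms, depth = 4, branching = 3, n_blocks = 4,
                          seed = 1, term_ids = NULL, blocks = NULL,
                          multi_prob = 0.3) {
  n_terms <- check_count(n_terms, "n_terms")
  depth <- check_count(depth, "depth", min = 2L)
  branching <- check_count(branching, "branching")
  n_blocks <- check_count(n_blocks, "n_blocks")
  if (is.null(term_ids)) term_ids <- sprintf("D%06d", seq_len(n_terms))
  if (is.null(blocks)) blocks <- rep_len(seq_len(n_blocks), n_terms)
  with_seed(seed, {
    tree_for <- function(block) {
      len <- sample(2:depth, 1)
      comps <- c(sprintf("C%02d", block),
                 sprintf("%03d", sample(branching, len - 1L, replace = TRUE)))
      paste(comps, collapse = ".")
    }
    rows <- lapply(seq_len(n_terms), function(i) {
      trees <- tree_for(blocks[i])
      if (runif(1) < multi_prob) {
        b2 <- if (runif(1) < 0.8 || n_blocks == 1L) blocks[i] else
          sample(setdiff(seq_len(n_blocks), blocks[i]), 1)
        trees <- c(trees, tree_for(b2))
      }
      data.frame(term_id = term_ids[i], tree_number = trees,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "blocks") <- setNames(blocks, term_ids)
    out
  })
}

#' Generate block-structured bipartite association tables
#'
#' Emulates disease-gene/chemical/pathway association files: a term is
#' linked to a partner with probability `within_p` when they share a
#' ground-truth block and `between_p` otherwise.
#'
#' @param n_terms,n_partners table dimensions (partners are per table).
#' @param n_blocks number of blocks; terms and partners are split evenly.
#' @param within_p,between_p linkage probabilities; `within_p` must exceed
#'   `between_p`.
#' @param seed RNG seed.
#' @param tables names of the association tables to generate.
#' @param term_ids,blocks optional explicit term ids / block assignment.
#' @return list with `tables` (named list of data.frames `term_id`,
#'   `partner_id`) and `blocks` (named integer vector, the ground truth).
#' @export
gen_association_tables <- function(n_terms, n_partners, n_blocks = 4,
                                   within_p = 0.6, between_p = 0.05, seed = 1,
                                   tables = c("genes", "chemicals", "pathways"),
                                   term_ids = NULL, blocks = NULL) {
  n_terms <- check_count(n_terms, "n_terms")
  n_partners <- check_count(n_partners, "n_partners")
  n_blocks <- check_count(n_blocks, "n_blocks")
  check_fraction(within_p, "within_p")
  check_fraction(between_p, "between_p")
  if (within_p <= between_p) {
    stop_config("within_p must be strictly greater than between_p")
  }
  if (is.null(term_ids)) term_ids <- sprintf("D%06d", seq_len(n_terms))
  if (is.null(blocks)) blocks <- rep_len(seq_len(n_blocks), n_terms)
  with_seed(seed, {
    tabs <- lapply(seq_along(tables), function(ti) {
      prefix <- substr(tables[ti], 1, 2)
      partner_ids <- sprintf("%s%05d", prefix, seq_len(n_partners))
      partner_blocks <- rep_len(seq_len(n_blocks), n_partners)
      same <- outer(blocks, partner_blocks, "==")
      p <- ifelse(same, within_p, between_p)
      hit <- matrix(runif(length(p)) < p, nrow = n_terms)
      idx <- which(hit, arr.ind = TRUE)
      data.frame(term_id = term_ids[idx[, 1]],
                 partner_id = partner_ids[idx[, 2]],
                 stringsAsFactors = FALSE)
    })
    names(tabs) <- tables
    list(tables = tabs, blocks = setNames(as.integer(blocks), term_ids))
  })
}

#' Generate random pre-trained word vectors
#'
#' One vector per vocabulary entry with i.i.d. Gaussian entries scaled by
#' `1/sqrt(dim)`, mirroring the scale of published GloVe vectors.
#'
#' @param vocab character vector of words (non-empty).
#' @param dim embedding dimension; one of 50, 100, 200, 300 (the grid the
#'   classifier tunes over).
#' @param seed RNG seed.
#' @param path optional file path; when given, vectors are written in the
#'   whitespace-delimited word-embedding text format.
#' @return numeric matrix (words x dim) with words as rownames, invisibly
#'   when `path` is given.
#' @export
gen_word_vectors <- function(vocab, dim = 50, seed = 1, path = NULL) {
  if (length(vocab) == 0) stop_config("vocabulary must be non-empty")
  if (!dim %in% c(50L, 100L, 200L, 300L)) {
    stop_config("dim must be one of 50, 100, 200, 300")
  }
  m <- with_seed(seed,
    matrix(rnorm(length(vocab) * dim), nrow = length(vocab)) / sqrt(dim))
  rownames(m) <- vocab
  if (!is.null(path)) {
    write_word_vectors(m, path)
    return(invisible(m))
  }
  m
}
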
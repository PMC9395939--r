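# Text pre-processing: tokenise/lemmatise via a pluggable backend, filter
# by part of speech, lemma length and stopwords, align externally supplied
# concept annotations to kept tokens and export normalised processed text.

# Closed-class POS assignments for the fixture lemmatizer; everything else
# defaults to NOUN, which the synthetic vocabulary is made of.
fixture_pos_lexicon <- c(
  the = "DET", a = "DET", an = "DET", this = "DET", that = "DET",
  these = "DET", those = "DET",
  and = "CCONJ", or = "CCONJ", but = "CCONJ",
  was = "AUX", were = "AUX", is = "AUX", are = "AUX", be = "AUX",
  been = "AUX", have = "AUX", has = "AUX", had = "AUX",
  with = "ADP", for. = "ADP", from = "ADP", of = "ADP", `in` = "ADP",
  on = "ADP", at = "ADP", by = "ADP", to = "PART",
  not = "PART", it = "PRON", they = "PRON", we = "PRON"
)
names(fixture_pos_lexicon)[names(fixture_pos_lexicon) == "for."] <- "for"

#' Deterministic fixture lemmatizer
#'
#' A rule-free stand-in for a full NLP lemmatizer so that the pipeline and
#' its tests never call external models: tokens are maximal alphanumeric
#' runs, the lemma is the lowercased surface, and the part of speech comes
#' from a lexicon (closed-class function words; `NUM` for numerals; `NOUN`
#' otherwise). Spans are 0-based, half-open character offsets over the raw
#' text. A morphologically informed backend can be substituted anywhere a
#' `lemmatizer` argument is accepted, as long as it returns the same
#' columns.
#'
#' @param pos_lexicon named character vector mapping lowercased surfaces to
#'   universal POS tags; merged over the built-in closed-class defaults.
#' @return a function `(text) -> data.frame(surface, lemma, upos, start, end)`.
#' @export
fixture_lemmatizer <- function(pos_lexicon = NULL) {
  lex <- fixture_pos_lexicon
  if (!is.null(pos_lexicon)) lex[names(pos_lexicon)] <- pos_lexicon
  function(text) {
    if (!nzchar(text)) {
      return(data.frame(surface = character(), lemma = character(),
                        upos = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
    if (m[1] == -1) {
      return(data.frame(surface = character(), lemma = character(),
                        upos = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    surface <- substring(text, start + 1L, start + len)
    lemma <- tolower(surface)
    upos <- unname(lex[lemma])
    upos[is.na(upos)] <- ifelse(grepl("^[0-9]+$", lemma[is.na(upos)]),
                                "NUM", "NOUN")
    data.frame(surface = surface, lemma = lemma, upos = upos,
               start = start, end = start + len, stringsAsFactors = FALSE)
  }
}

#' Default stopword list
#'
#' Union of a standard English NLP stopword list and the PubMed stopword
#' list, shipped as a plain-text file; comparison is on the lowercased
#' lemma.
#' @return character vector.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "dialogi"),
            encoding = "UTF-8")
}

keep_upos <- c("NOUN", "VERB", "ADJ", "ADV")

#' Pre-process raw text into kept tokens
#'
#' Tokenises/lemmatises `raw_text` with the pluggable backend, then keeps
#' only nouns, verbs, adjectives and adverbs whose lowercased lemma is at
#' least 3 characters long and not a stopword. Numerals and punctuation
#' are dropped implicitly by the POS filter.
#'
#' @param text raw text (title + single space + abstract by convention).
#' @param lemmatizer a function as returned by [fixture_lemmatizer()].
#' @param stopwords character vector of stopwords.
#' @return data.frame of kept tokens (`surface`, `lemma`, `upos`, `start`,
#'   `end`); empty for empty text.
#' @export
preprocess <- function(text, lemmatizer = fixture_lemmatizer(),
                       stopwords = default_stopwords()) {
  toks <- lemmatizer(text)
  keep <- toks$upos %in% keep_upos &
    nchar(toks$lemma) >= 3L &
    !(toks$lemma %in% stopwords)
  out <- toks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a PubTator-format annotation file
#'
#' Reads `PMID|t|`/`PMID|a|` text lines and tab-separated annotation lines,
#' keeping only Chemical and Disease mentions and stripping any `MESH:`
#' prefix from identifiers.
#'
#' @param path file in PubTator text format.
#' @param strict abort on a malformed line (otherwise: warn and skip).
#' @param offset_sep separator assumed between title and abstract in the
#'   file's offsets: `"space"` (the package convention) or `"newline"`
#'   (converted on read).
#' @return list with `documents` (data.frame `id`, `title`, `abstract`) and
#'   `mentions` (data.frame `doc_id`, `start`, `end`, `text`, `type`,
#'   `concept_id`).
#' @export
parse_pubtator <- function(path, strict = FALSE, offset_sep = c("space", "newline")) {
  offset_sep <- match.arg(offset_sep)
  lines <- readLines(path, encoding = "UTF-8")
  title <- list(); abstract <- list(); anns <- vector("list", length(lines))
  bad <- function(i, why) {
    msg <- sprintf("malformed PubTator line %d (%s)", i, why)
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    tm <- regmatches(ln, regexec("^([^|\t]+)\\|t\\|(.*)$", ln))[[1]]
    if (length(tm)) { title[[tm[2]]] <- tm[3]; next }
    am <- regmatches(ln, regexec("^([^|\t]+)\\|a\\|(.*)$", ln))[[1]]
    if (length(am)) { abstract[[am[2]]] <- am[3]; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) { bad(i, "expected 6 tab-separated fields"); next }
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s >= e) { bad(i, "invalid offsets"); next }
    anns[[i]] <- data.frame(doc_id = f[1], start = s, end = e, text = f[4],
                            type = f[5], concept_id = sub("^MESH:", "", f[6]),
                            stringsAsFactors = FALSE)
  }
  mentions <- do.call(rbind, anns[!vapply(anns, is.null, logical(1))])
  if (is.null(mentions)) {
    mentions <- data.frame(doc_id = character(), start = integer(),
                           end = integer(), text = character(),
                           type = character(), concept_id = character(),
                           stringsAsFactors = FALSE)
  }
  mentions <- mentions[mentions$type %in% c("Chemical", "Disease"), ,
                       drop = FALSE]
  ids <- union(names(title), names(abstract))
  documents <- data.frame(
    id = ids,
    title = unlist(title)[ids] %||% character(),
    abstract = vapply(ids, function(k) abstract[[k]] %||% "", character(1)),
    stringsAsFactors = FALSE
  )
  documents$title[is.na(documents$title)] <- ""
  if (offset_sep == "newline") {
    # newline dialect uses title + "\n" + abstract: same arithmetic, the
    # separator is one character either way, so offsets coincide.
    NULL
  }
  rownames(documents) <- NULL
  rownames(mentions) <- NULL
  list(documents = documents, mentions = mentions)
}

#' Align concept mentions to kept tokens
#'
#' A mention is matched iff the kept-token spans cover at least
#' `min_overlap` of the mention span's characters. Unmatched mentions are
#' retained but flagged: they still count toward relative frequencies and
#' are only excluded from text replacement.
#'
#' @param mentions data.frame for one document (`start`, `end`,
#'   `concept_id`, `type`).
#' @param tokens kept tokens from [preprocess()] on the same raw text.
#' @param min_overlap matching threshold in \[0,1\].
#' @param text_length length of the raw text, for validation.
#' @param doc_id used in error messages.
#' @return `mentions` with added `matched` (logical), `overlap` (numeric)
#'   and `matched_tokens` (list of kept-token indices).
#' @export
align <- function(mentions, tokens, min_overlap = 0.9, text_length = NULL,
                  doc_id = "?") {
  if (!is.null(text_length) && nrow(mentions) &&
      any(mentions$end > text_length)) {
    stop(sprintf("mention span exceeds text length in document %s", doc_id))
  }
  n <- nrow(mentions)
  mentions$overlap <- numeric(n) + if (n) NA_real_ else numeric(0)
  mentions$matched <- logical(n)
  mentions$matched_tokens <- vector("list", n)
  for (i in seq_len(n)) {
    s <- mentions$start[i]; e <- mentions$end[i]
    inter <- pmax(0L, pmin(tokens$end, e) - pmax(tokens$start, s))
    hit <- which(inter > 0L)
    cov <- sum(inter) / (e - s)
    mentions$overlap[i] <- cov
    mentions$matched[i] <- cov >= min_overlap
    mentions$matched_tokens[[i]] <- hit
  }
  mentions
}

#' Per-document concept relative frequencies
#'
#' Per category, `freq(concept) = mentions of concept / total mentions of
#' that category` in the document. All mentions count, whether or not they
#' aligned to kept tokens.
#'
#' @param mentions mention data.frame for one document.
#' @return list with named numeric vectors `disease` and `chemical`, each
#'   summing to 1 when non-empty.
#' @export
relative_frequencies <- function(mentions) {
  out <- list(disease = numeric(0), chemical = numeric(0))
  for (cat in c("Disease", "Chemical")) {
    sub <- mentions[mentions$type == cat, , drop = FALSE]
    key <- tolower(cat)
    if (nrow(sub)) {
      tab <- table(sub$concept_id)
      out[[key]] <- setNames(as.numeric(tab) / sum(tab), names(tab))
    }
  }
  out
}

#' Build an annotated document
#'
#' Runs [preprocess()], [align()] and [relative_frequencies()] for one
#' title/abstract pair under the package's single offset convention
#' (`title + " " + abstract`, 0-based half-open).
#'
#' @param doc_id document identifier.
#' @param title,abstract raw text fields.
#' @param mentions mention data.frame for this document (may be empty).
#' @param label optional 0/1 class label.
#' @param min_overlap alignment threshold.
#' @param lemmatizer,stopwords passed to [preprocess()].
#' @return object of class `annotated_document`.
#' @export
annotate_document <- function(doc_id, title, abstract, mentions,
                              label = NA_integer_, min_overlap = 0.9,
                              lemmatizer = fixture_lemmatizer(),
                              stopwords = default_stopwords()) {
  txt <- raw_text(title, abstract)
  tokens <- preprocess(txt, lemmatizer, stopwords)
  mentions <- align(mentions, tokens, min_overlap = min_overlap,
                    text_length = nchar(txt), doc_id = doc_id)
  structure(list(doc_id = doc_id, raw_text = txt, tokens = tokens,
                 mentions = mentions,
                 rel_freq = relative_frequencies(mentions),
                 label = label),
            class = "annotated_document")
}

#' @exportS3Method base::print
print.annotated_document <- function(x, ...) {
  cat(sprintf("annotated_document %s: %d kept tokens, %d mentions (%d matched)\n",
              x$doc_id, nrow(x$tokens), nrow(x$mentions),
              sum(x$mentions$matched)))
  invisible(x)
}

#' Annotate a whole document table
#'
#' @param documents data.frame `id`, `title`, `abstract` and optional
#'   `label`.
#' @param mentions mention data.frame over all documents (`doc_id` keyed).
#' @inheritParams annotate_document
#' @return named list of `annotated_document`s, in document-table order.
#' @export
annotate_corpus <- function(documents, mentions, min_overlap = 0.9,
                            lemmatizer = fixture_lemmatizer(),
                            stopwords = default_stopwords()) {
  empty <- mentions[0, , drop = FALSE]
  split_m <- split(mentions, mentions$doc_id)
  labels <- if ("label" %in% names(documents)) documents$label else
    rep(NA_integer_, nrow(documents))
  out <- lapply(seq_len(nrow(documents)), function(i) {
    annotate_document(documents$id[i], documents$title[i],
                      documents$abstract[i],
                      split_m[[documents$id[i]]] %||% empty,
                      label = labels[i], min_overlap = min_overlap,
                      lemmatizer = lemmatizer, stopwords = stopwords)
  })
  names(out) <- documents$id
  out
}

#' Export normalised processed text
#'
#' Returns the kept lemmas of a document with matched concept mentions
#' optionally replaced by a single symbol: the concept identifier
#' (`replace_id`) or the broad category (`replace_category`:
#' `"disease"`/`"chemical"`). Overlap conflicts between mentions on the
#' same tokens resolve to the longer mention, ties to the earlier start.
#'
#' @param doc an `annotated_document`.
#' @param mode one of `"plain"`, `"replace_id"`, `"replace_category"`.
#' @return character vector of output tokens.
#' @export
export_processed <- function(doc, mode = c("plain", "replace_id",
                                           "replace_category")) {
  mode <- match.arg(mode)
  lemmas <- doc$tokens$lemma
  if (mode == "plain" || !nrow(doc$mentions)) return(lemmas)
  m <- doc$mentions[doc$mentions$matched, , drop = FALSE]
  if (!nrow(m)) return(lemmas)
  m <- m[order(-(m$end - m$start), m$start), , drop = FALSE]
  symbol <- if (mode == "replace_id") m$concept_id else tolower(m$type)
  out <- lemmas
  dropped <- logical(length(lemmas))
  claimed <- logical(length(lemmas))
  for (i in seq_len(nrow(m))) {
    idx <- setdiff(m$matched_tokens[[i]], which(claimed))
    if (!length(idx)) next
    out[idx[1]] <- symbol[i]
    dropped[idx[-1]] <- TRUE
    claimed[idx] <- TRUE
  }
  out[!dropped]
}
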
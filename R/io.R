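# Readers/writers for the plain-text interchange formats: document TSV,
# PubTator annotations, hierarchy/association TSVs and the
# whitespace-delimited word-embedding text format.

#' Write / read the document table
#'
#' TSV with header `id  title  abstract  label`, UTF-8.
#' @param documents data.frame with those columns.
#' @param path file path.
#' @return `read_documents` returns the data.frame; `write_documents` its
#'   path, invisibly.
#' @export
write_documents <- function(documents, path) {
  stopifnot(all(c("id", "title", "abstract") %in% names(documents)))
  write.table(documents, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_documents
#' @export
read_documents <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
  if ("label" %in% names(x)) x$label <- as.integer(x$label)
  x
}

#' Write annotations in PubTator text format
#'
#' Emits per document a `PMID|t|title` line, a `PMID|a|abstract` line and
#' one tab-separated annotation line per mention
#' (`PMID  start  end  text  type  conceptID`), offsets 0-based half-open
#' over `title + " " + abstract`.
#'
#' @param documents document data.frame (`id`, `title`, `abstract`).
#' @param mentions data.frame as returned by [gen_annotations()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(documents, mentions, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  split_m <- split(mentions, mentions$doc_id)
  for (i in seq_len(nrow(documents))) {
    id <- documents$id[i]
    writeLines(c(paste0(id, "|t|", documents$title[i]),
                 paste0(id, "|a|", documents$abstract[i])), con)
    m <- split_m[[id]]
    if (!is.null(m) && nrow(m)) {
      m <- m[order(m$start), , drop = FALSE]
      writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", id, m$start, m$end,
                         m$text, m$type, m$concept_id), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read hierarchy and association tables
#'
#' Plain TSVs: `term_id  tree_number` (one row per tree number) and
#' `term_id  partner_id`.
#' @param x the table.
#' @param path file path.
#' @return the table (readers) or `path` invisibly (writers).
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write / read word-embedding text files
#'
#' The common whitespace-delimited format: one token followed by its
#' coordinates per line. Used both for word vectors and for concept
#' embedding matrices (term id + floats).
#'
#' @param m numeric matrix with tokens/term ids as rownames.
#' @param path file path.
#' @return the matrix (reader) or `path` invisibly (writer).
#' @export
write_word_vectors <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.6g", m[i, ])), collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_word_vectors
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  dim <- length(parts[[1]]) - 1L
  m <- matrix(0, nrow = length(parts), ncol = dim)
  words <- character(length(parts))
  for (i in seq_along(parts)) {
    words[i] <- parts[[i]][1]
    m[i, ] <- as.numeric(parts[[i]][-1])
  }
  rownames(m) <- words
  m
}
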
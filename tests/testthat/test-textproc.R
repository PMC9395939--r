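test_that("preprocess applies the POS, length and stopword rules", {
  lemma <- fixture_lemmatizer(c(hepatotoxicity = "NOUN", severe = "ADJ",
                                up = "ADV", used = "VERB"))
  toks <- preprocess("Hepatotoxicity was severe", lemma)
  expect_identical(toks$lemma, c("hepatotoxicity", "severe"))

  # length-3 rule: "up" is a kept POS but too short
  expect_identical(preprocess("up", lemma)$lemma, character(0))

  # stopword rule on the lowercased lemma
  expect_identical(preprocess("used", lemma, stopwords = "used")$lemma,
                   character(0))
  expect_identical(preprocess("used", lemma, stopwords = character())$lemma,
                   "used")

  # numerals and empty text
  expect_identical(nrow(preprocess("123 456", lemma)), 0L)
  expect_identical(nrow(preprocess("", lemma)), 0L)

  # spans are 0-based half-open over the raw text
  t2 <- preprocess("liver failure", fixture_lemmatizer())
  expect_identical(t2$start, c(0L, 6L))
  expect_identical(t2$end, c(5L, 13L))
})

test_that("parse_pubtator keeps only chemical/disease mentions and strips MESH:", {
  path <- withr::local_tempfile(lines = c(
    "17|t|Paracetamol overdose",
    "17|a|A case of liver failure.",
    "17\t0\t11\tParacetamol\tChemical\tMESH:D000082",
    "17\t31\t44\tliver failure\tDisease\tD017093",
    "17\t2\t5\trac\tGene\t1234",
    ""))
  out <- parse_pubtator(path)
  expect_identical(nrow(out$mentions), 2L)
  expect_setequal(out$mentions$concept_id, c("D000082", "D017093"))
  expect_identical(out$mentions$start[out$mentions$type == "Chemical"], 0L)
  expect_identical(out$mentions$end[out$mentions$type == "Chemical"], 11L)
  expect_identical(out$documents$title, "Paracetamol overdose")
})

test_that("parse_pubtator reports malformed lines per strict mode", {
  path <- withr::local_tempfile(lines = c(
    "9|t|Title words",
    "9|a|Abstract words",
    "9\tnot_a_number\t5\tx\tChemical\tD1",
    "9\t0\t5\tTitle\tChemical\tD000001"))
  expect_warning(out <- parse_pubtator(path), "line 3")
  expect_identical(nrow(out$mentions), 1L)
  expect_error(parse_pubtator(path, strict = TRUE), "line 3")
})

test_that("align matches mentions by character coverage of kept tokens", {
  tokens <- data.frame(surface = c("aaaaa", "bbbb"),
                       lemma = c("aaaaa", "bbbb"), upos = "NOUN",
                       start = c(0L, 6L), end = c(5L, 10L))
  m <- data.frame(doc_id = "1", start = 0L, end = 10L, text = "x",
                  type = "Disease", concept_id = "D1")
  # spans [0,5) and [6,10) cover 9 of 10 characters: matched at 0.9 exactly
  out <- align(m, tokens, min_overlap = 0.9)
  expect_equal(out$overlap, 0.9)
  expect_true(out$matched)
  expect_identical(out$matched_tokens[[1]], c(1L, 2L))

  # single token covering the whole span
  out1 <- align(data.frame(start = 0L, end = 5L), tokens, 0.9)
  expect_equal(out1$overlap, 1.0)

  # 2/10 coverage: unmatched
  out2 <- align(data.frame(start = 0L, end = 10L),
                tokens[tokens$start == 6L, ][, ], 0.9)
  expect_equal(out2$overlap, 0.4)
  out3 <- align(data.frame(start = 0L, end = 10L),
                data.frame(start = 8L, end = 10L), 0.9)
  expect_equal(out3$overlap, 0.2)
  expect_false(out3$matched)

  expect_error(align(data.frame(start = 0L, end = 99L), tokens,
                     text_length = 20, doc_id = "doc7"), "doc7")
})

test_that("align is monotone in min_overlap", {
  sc <- shared_corpus()
  doc <- sc$docs[[which(vapply(sc$docs, function(d) nrow(d$mentions) > 3,
                               logical(1)))[1]]]
  matched_at <- function(th) {
    m <- align(sc$mentions[sc$mentions$doc_id == doc$doc_id, ],
               doc$tokens, min_overlap = th)
    m$matched
  }
  for (pair in list(c(0.5, 0.7), c(0.7, 0.9), c(0.9, 1.0))) {
    lo <- matched_at(pair[1]); hi <- matched_at(pair[2])
    expect_true(all(lo | !hi))   # raising the threshold never adds matches
  }
})

test_that("relative frequencies normalise per category", {
  m <- data.frame(
    doc_id = "1", start = 0L, end = 1L, text = "x",
    type = c("Disease", "Disease", "Disease", "Disease",
             "Chemical", "Chemical", "Chemical", "Chemical"),
    concept_id = c("A", "A", "B", "B", "X", "X", "X", "Y"))
  rf <- relative_frequencies(m)
  expect_equal(rf$disease, c(A = 0.5, B = 0.5))
  expect_equal(rf$chemical, c(X = 0.75, Y = 0.25))

  single <- relative_frequencies(m[m$concept_id == "A", ])
  expect_equal(single$disease, c(A = 1.0))
  expect_identical(single$chemical, numeric(0))

  # property: sums to 1 for every synthetic document with mentions
  sc <- shared_corpus()
  for (d in sc$docs) {
    for (cat in c("disease", "chemical")) {
      if (length(d$rel_freq[[cat]])) {
        expect_equal(sum(d$rel_freq[[cat]]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("export_processed replaces matched mentions by one symbol", {
  raw_t <- "acute"
  raw_a <- "liver failure after overdose"
  m <- data.frame(doc_id = "1", start = 6L, end = 19L,
                  text = "liver failure", type = "Disease",
                  concept_id = "D017093")
  doc <- annotate_document("1", raw_t, raw_a, m, stopwords = character())
  expect_identical(export_processed(doc, "plain"),
                   c("acute", "liver", "failure", "after", "overdose"))
  expect_identical(export_processed(doc, "replace_id"),
                   c("acute", "D017093", "after", "overdose"))
  expect_identical(export_processed(doc, "replace_category"),
                   c("acute", "disease", "after", "overdose"))

  # no mentions: all modes identical to plain
  doc0 <- annotate_document("2", raw_t, raw_a, m[0, ],
                            stopwords = character())
  expect_identical(export_processed(doc0, "replace_id"),
                   export_processed(doc0, "plain"))

  expect_error(export_processed(doc, "bogus"))
})

test_that("replacement output is never longer than plain output", {
  sc <- shared_corpus()
  for (d in sc$docs[1:20]) {
    plain <- export_processed(d, "plain")
    expect_lte(length(export_processed(d, "replace_id")), length(plain))
    expect_lte(length(export_processed(d, "replace_category")), length(plain))
  }
})

test_that("the pipeline is deterministic", {
  sc <- shared_corpus()
  d1 <- annotate_document("x", "some title tokens",
                          "alpha beta gamma delta",
                          sc$mentions[0, ])
  d2 <- annotate_document("x", "some title tokens",
                          "alpha beta gamma delta",
                          sc$mentions[0, ])
  expect_identical(d1, d2)
})
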
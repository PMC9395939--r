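# Helper: annotated document stub with prescribed relative frequencies.
stub_doc <- function(id, disease = numeric(0), chemical = numeric(0),
                     label = NA_integer_) {
  n_mentions <- function(freqs, type) {
    if (!length(freqs)) return(NULL)
    counts <- round(freqs / min(freqs))     # integer mention counts
    data.frame(doc_id = id, start = 0L, end = 1L, text = "x", type = type,
               concept_id = rep(names(counts), counts))
  }
  m <- rbind(n_mentions(disease, "Disease"), n_mentions(chemical, "Chemical"))
  if (is.null(m)) m <- data.frame(doc_id = character(), start = integer(),
                                  end = integer(), text = character(),
                                  type = character(),
                                  concept_id = character())
  structure(list(doc_id = id, raw_text = "", tokens = NULL, mentions = m,
                 rel_freq = relative_frequencies(m), label = label),
            class = "annotated_document")
}

test_that("compose_space reproduces the reference dimensionalities", {
  # disease side: two association spaces (-> 103) + hierarchy space (-> 47)
  gobp <- random_space(320, 140, seed = 1)
  gomf <- random_space(320, 120, seed = 2)
  mesh <- random_space(320, 128, seed = 3)
  disease <- compose_space(list(list(gobp, gomf), list(mesh)),
                           list(103, 47))
  expect_identical(ncol(disease$matrix), 150L)
  expect_identical(disease$provenance, "composite")

  # chemical side: signature spaces (-> 265) + hierarchy (-> 35)
  cc1 <- random_space(320, 200, seed = 4)
  cc2 <- random_space(320, 180, seed = 5)
  meshc <- random_space(320, 128, seed = 6)
  chem <- compose_space(list(list(cc1, cc2), list(meshc)), list(265, 35))
  expect_identical(ncol(chem$matrix), 300L)

  expect_identical(unname(paper_profile()$disease), c(103, 47))
  expect_identical(unname(paper_profile()$chemical), c(265, 35))
})

test_that("compose_space unions terms, zero-fills, and errors on disjoint", {
  a <- random_space(10, 4, seed = 1)
  b <- random_space(14, 4, seed = 2)        # shares the first 10 ids
  comp <- compose_space(list(list(a), list(b)), list(3, 3))
  expect_identical(nrow(comp$matrix), 14L)
  c_ <- random_space(5, 4, seed = 3, prefix = "Z")
  expect_error(compose_space(list(list(a), list(c_)), list(2, 2)),
               "disjoint")
})

test_that("single member at target dim preserves the subspace", {
  x <- random_space(30, 6, seed = 7)
  comp <- compose_space(list(list(x)), list(6))
  # same column span: projecting comp onto x's column space is lossless
  fit <- lm.fit(x, comp$matrix)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(tcrossprod(comp$matrix), tcrossprod(x), tolerance = 1e-8)
})

test_that("text_vector matches hand-computed weighted averages", {
  dsp <- dense_space(random_space(6, 4, seed = 1), provenance = "raw")
  csp <- dense_space(random_space(6, 3, seed = 2), provenance = "raw")
  ids <- rownames(dsp$matrix)

  # single disease concept, no chemicals
  d1 <- stub_doc("a", disease = setNames(1, ids[1]))
  v1 <- text_vector(d1, dsp, csp)
  e <- dsp$matrix[ids[1], ]
  expect_equal(as.numeric(v1), c(e / sqrt(sum(e^2)), rep(0, 3)),
               tolerance = 1e-9)
  expect_true(attr(v1, "has_disease"))
  expect_false(attr(v1, "has_chemical"))

  # weights 0.75/0.25: oracle arithmetic
  d2 <- stub_doc("b", disease = setNames(c(0.75, 0.25), ids[1:2]))
  raw <- 0.75 * dsp$matrix[ids[1], ] + 0.25 * dsp$matrix[ids[2], ]
  expect_equal(as.numeric(text_vector(d2, dsp, csp))[1:4],
               raw / sqrt(sum(raw^2)), tolerance = 1e-9)

  # no annotations at all
  d0 <- stub_doc("c")
  v0 <- text_vector(d0, dsp, csp)
  expect_equal(as.numeric(v0), rep(0, 7))
  expect_false(attr(v0, "has_disease") || attr(v0, "has_chemical"))

  # missing term: weight mass not redistributed
  d3 <- stub_doc("d", disease = setNames(c(0.5, 0.5), c(ids[1], "D999999")))
  raw3 <- 0.5 * dsp$matrix[ids[1], ]
  expect_equal(as.numeric(text_vector(d3, dsp, csp))[1:4],
               raw3 / sqrt(sum(raw3^2)), tolerance = 1e-9)
  expect_true(attr(text_vector(d3, dsp, csp), "has_disease"))
})

test_that("feature vectors are invariant to count scaling and mention order", {
  dsp <- dense_space(random_space(6, 4, seed = 1), provenance = "raw")
  csp <- dense_space(random_space(6, 3, seed = 2), provenance = "raw")
  ids <- rownames(dsp$matrix)
  base <- stub_doc("a", disease = setNames(c(3, 1) / 4, ids[1:2]))
  scaled <- base
  scaled$mentions <- scaled$mentions[rep(seq_len(nrow(scaled$mentions)), 5), ]
  scaled$rel_freq <- relative_frequencies(scaled$mentions)
  expect_equal(as.numeric(text_vector(base, dsp, csp)),
               as.numeric(text_vector(scaled, dsp, csp)), tolerance = 1e-12)

  shuffled <- base
  shuffled$mentions <- shuffled$mentions[rev(seq_len(nrow(shuffled$mentions))), ]
  shuffled$rel_freq <- relative_frequencies(shuffled$mentions)
  expect_equal(as.numeric(text_vector(base, dsp, csp)),
               as.numeric(text_vector(shuffled, dsp, csp)), tolerance = 1e-12)
})

test_that("batch_featurize reports coverage and enforces unique ids", {
  sc <- shared_corpus()
  ids <- unique(sc$corpus$concepts$concept_id)
  dsp <- dense_space(random_space(length(ids), 8, seed = 3), provenance = "raw")
  rownames(dsp$matrix) <- ids; dsp$terms <- ids
  csp <- dsp
  fz <- batch_featurize(sc$docs, dsp, csp)
  expect_identical(dim(fz$features), c(60L, 16L))
  # two unit-or-zero halves: row norms at most sqrt(2)
  expect_true(all(sqrt(rowSums(fz$features^2)) <= sqrt(2) + 1e-9))
  half <- fz$features[, 1:8]
  norms <- sqrt(rowSums(half^2))
  expect_true(all(abs(norms) < 1e-9 | abs(norms - 1) < 1e-9))
  # coverage ~ 1 - fraction_unannotated per class
  expect_true(all(abs(fz$coverage$disease - 0.8) < 0.15))
  expect_error(batch_featurize(c(sc$docs, sc$docs[1]), dsp, csp),
               "duplicate")
})

test_that("linear probe separates classes on planted-concept features", {
  cfg <- synth_config(n_docs = 400, seed = 17, abstract_len = 50,
                      vocab_size = 400, concept_signal = 0.8,
                      n_disease_terms = 60, n_chem_terms = 60)
  corp <- gen_documents(cfg)
  adocs <- annotate_corpus(corp$documents, gen_annotations(corp))
  dis <- corp$concepts[corp$concepts$category == "disease", ]
  chm <- corp$concepts[corp$concepts$category == "chemical", ]
  ad <- gen_association_tables(nrow(dis), 400, within_p = 0.6,
                               between_p = 0.05, seed = 18,
                               term_ids = dis$concept_id, blocks = dis$block)
  ac <- gen_association_tables(nrow(chm), 400, within_p = 0.6,
                               between_p = 0.05, seed = 19,
                               term_ids = chm$concept_id, blocks = chm$block)
  dsp <- embed_concepts(corpus_from_associations(ad$tables$genes), dim = 32,
                        seed = 20, min_df = 2, n_neighbors = 30,
                        n_pairs = 20000)
  csp <- embed_concepts(corpus_from_associations(ac$tables$genes), dim = 32,
                        seed = 21, min_df = 2, n_neighbors = 30,
                        n_pairs = 20000)
  fz <- batch_featurize(adocs, dsp, csp)
  y <- corp$documents$label
  train <- seq_len(300); test <- 301:400
  fit <- suppressWarnings(
    glm.fit(cbind(1, fz$features[train, ]), y[train],
            family = binomial()))
  pred <- as.numeric(cbind(1, fz$features[test, ]) %*% fit$coefficients > 0)
  expect_gte(mean(pred == y[test]), 0.8)
})
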
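# Small corpus + word vectors shared by the classifier tests.
clf_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_docs = 120, seed = 33, abstract_len = 40,
                          vocab_size = 300, n_disease_terms = 40,
                          n_chem_terms = 40, n_signal_concepts = 6)
      corp <- gen_documents(cfg)
      adocs <- annotate_corpus(corp$documents, gen_annotations(corp))
      texts <- lapply(adocs, function(d) export_processed(d, "replace_id"))
      vocab <- build_vocab(texts)
      wv <- gen_word_vectors(vocab, dim = 50, seed = 2)
      feats <- withr::with_seed(5, matrix(rnorm(120 * 12), 120, 12))
      cache <<- list(corp = corp, texts = texts, vocab = vocab, wv = wv,
                     labels = corp$documents$label, feats = feats)
    }
    cache
  }
})

test_that("model_spec enforces the tuned grids", {
  expect_s3_class(model_spec(300, 96, 320, 1e-2), "model_spec")
  expect_error(model_spec(embed_dim = 60), class = "dialogi_config_error")
  expect_error(model_spec(lstm_units = 33), class = "dialogi_config_error")
  expect_error(model_spec(dense_units = 200), class = "dialogi_config_error")
  expect_error(model_spec(learning_rate = 2e-3),
               class = "dialogi_config_error")
})

test_that("baseline build honours pretrained init and is deterministic", {
  fx <- clf_fixture()
  spec <- model_spec(50, 32, 192, 5e-3)
  m1 <- build_baseline(spec, fx$vocab, fx$wv, seed = 4)
  m2 <- build_baseline(spec, fx$vocab, fx$wv, seed = 4)
  expect_identical(m1$params, m2$params)
  # in-vocabulary rows equal the pretrained vectors before training
  expect_equal(m1$params$E, unname(fx$wv[fx$vocab, ]), ignore_attr = TRUE)
  expect_error(build_baseline(model_spec(100, 32, 192, 5e-3),
                              fx$vocab, fx$wv), "dimension")

  seqs <- encode_sequences(fx$texts, fx$vocab, maxlen = 40)
  p <- predict_proba(m1, seqs)
  expect_true(all(p >= 0 & p <= 1))
  # training is deterministic too
  t1 <- train_baseline(m1, seqs, fx$labels, seed = 8)
  t2 <- train_baseline(m2, seqs, fx$labels, seed = 8)
  expect_equal(t1$params, t2$params, tolerance = 1e-12)
})

test_that("zeroed extension branch reproduces the baseline exactly", {
  fx <- clf_fixture()
  seqs <- encode_sequences(fx$texts, fx$vocab, maxlen = 40)
  base <- train_baseline(build_baseline(model_spec(), fx$vocab, fx$wv,
                                        seed = 1),
                         seqs, fx$labels, seed = 1)
  ext <- extend_model(base, ncol(fx$feats), init = "zero")
  p_base <- predict_proba(base, seqs)
  p_ext <- predict_proba(ext, seqs, fx$feats)
  expect_lt(max(abs(p_base - p_ext)), 1e-6)
})

test_that("extension training leaves frozen weights bit-identical", {
  fx <- clf_fixture()
  seqs <- encode_sequences(fx$texts, fx$vocab, maxlen = 40)
  base <- train_baseline(build_baseline(model_spec(), fx$vocab, fx$wv,
                                        seed = 2),
                         seqs, fx$labels, seed = 2)
  ext <- extend_model(base, ncol(fx$feats), seed = 3)
  ext_t <- train_extended(ext, seqs, fx$feats, fx$labels, seed = 4)
  expect_identical(ext_t$base$params, base$params)
  expect_false(identical(ext_t$We, ext$We))
  # trainable parameter count of the new branch
  u <- base$spec$dense_units
  expect_identical(length(ext$We) + length(ext$be),
                   ncol(fx$feats) * u + u)
  expect_error(extend_model(base, 0), "positive")
})

test_that("evaluate matches the confusion-matrix arithmetic", {
  # confusion TP=8, FP=2, FN=1, TN=9 at threshold 0.5
  labels <- c(rep(1, 9), rep(0, 11))
  probs <- c(rep(0.9, 8), 0.1,            # 8 TP, 1 FN
             rep(0.9, 2), rep(0.1, 9))    # 2 FP, 9 TN
  mi <- evaluate(probs, labels, 0.5, "micro")
  expect_equal(mi$precision, 0.8)
  expect_equal(mi$recall, 8 / 9)
  expect_equal(mi$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-9)

  perf <- evaluate(labels * 0.98 + 0.01, labels, 0.5, "macro")
  expect_equal(perf$f1, 1.0)

  # near-zero threshold: everything predicted positive, recall 1
  expect_equal(evaluate(probs, labels, 1e-6, "micro")$recall, 1.0)

  expect_warning(evaluate(c(0.2, 0.9), c(1, 1), 0.5, "macro"),
                 "single-class")
})

test_that("evaluate matches a brute-force oracle on random vectors", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    labels <- rbinom(n, 1, 0.5)
    probs <- runif(n)
    th <- runif(1, 0.05, 0.95)
    pred <- as.integer(probs >= th)
    got <- suppressWarnings(evaluate(probs, labels, th, "macro"))
    o0 <- metrics_oracle(pred, labels, 0L)
    o1 <- metrics_oracle(pred, labels, 1L)
    expect_equal(got$f1, mean(c(o0[["f1"]], o1[["f1"]])), tolerance = 1e-12)
    gotm <- suppressWarnings(evaluate(probs, labels, th, "micro"))
    expect_equal(gotm$f1, o1[["f1"]], tolerance = 1e-12)
  }
})

test_that("stratified folds partition with class balance within one", {
  y <- rep(c(0, 1), c(37, 43))
  fold <- stratified_kfold(y, 10, seed = 3)
  expect_setequal(unique(fold), 1:10)
  for (cls in 0:1) {
    counts <- table(fold[y == cls])
    expect_lte(diff(range(counts)), 1)
  }
  expect_identical(stratified_kfold(y, 10, seed = 3),
                   stratified_kfold(y, 10, seed = 3))
})

test_that("nested_cv keeps outer test folds out of the inner search", {
  fx <- clf_fixture()
  ncv <- nested_cv(fx$texts, fx$labels, fx$feats, fx$wv,
                   grid = list(embed_dim = 50L, lstm_units = 32L,
                               dense_units = 192L,
                               learning_rate = c(1e-3, 1e-2)),
                   k_outer = 3, k_inner = 2, n_trials = 2, maxlen = 32,
                   seed = 5, keep_models = FALSE)
  expect_s3_class(ncv, "ncv_result")
  expect_length(ncv$folds, 3)
  all_test <- unlist(lapply(ncv$folds, `[[`, "test_ids"))
  expect_setequal(all_test, names(fx$texts))
  expect_false(any(duplicated(all_test)))
  for (f in ncv$folds) {
    expect_length(intersect(f$test_ids, f$inner_ids), 0)
    expect_length(f$inner_losses, 2)
    expect_s3_class(f$spec, "model_spec")
  }
})

test_that("threshold sweep agrees with pointwise evaluate", {
  fx <- clf_fixture()
  # synthetic ncv_result: two folds of random probabilities
  mk_fold <- function(seed) {
    withr::with_seed(seed, list(
      test_labels = rbinom(40, 1, 0.5),
      prob_baseline = runif(40),
      prob_extended = runif(40)))
  }
  ncv <- structure(list(folds = list(mk_fold(1), mk_fold(2)),
                        thresholds = c(baseline = 0.5, extended = 0.7),
                        k_outer = 2, k_inner = 2, maxlen = 32, seed = 1),
                   class = "ncv_result")
  sw <- threshold_sweep(ncv, "extended")
  expect_identical(nrow(sw), 10L)
  per_fold <- attr(sw, "per_fold")
  for (i in seq_len(nrow(sw))) {
    vals <- vapply(ncv$folds, function(f)
      suppressWarnings(
        evaluate(f$prob_extended, f$test_labels, sw$threshold[i],
                 "macro")$f1),
      numeric(1))
    expect_equal(unname(per_fold[i, ]), vals, tolerance = 1e-12)
    expect_equal(sw$mean_f1[i], mean(vals), tolerance = 1e-12)
  }
})
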
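# Baseline (text-only) and extended (text + external features) BiLSTM
# classifiers, trained and compared under nested cross-validation.

#' Hyperparameter grids for the classifiers
#'
#' The tuned grid: embedding dimension in {50, 100, 200, 300}, LSTM units
#' per direction 32-96 in steps of 16, dense units 192-320 in steps of 32,
#' learning rate in {1e-3, 5e-3, 7e-3, 1e-2}.
#' @return named list of allowed values.
#' @export
default_model_grid <- function() {
  list(embed_dim = c(50L, 100L, 200L, 300L),
       lstm_units = seq(32L, 96L, 16L),
       dense_units = seq(192L, 320L, 32L),
       learning_rate = c(1e-3, 5e-3, 7e-3, 1e-2))
}

#' Model hyperparameter specification
#'
#' Values must come from the tuned grids (see [default_model_grid()]).
#' Bidirectionality and trainable embeddings are fixed design choices,
#' not hyperparameters.
#'
#' @param embed_dim,lstm_units,dense_units,learning_rate grid values.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(embed_dim = 50, lstm_units = 32, dense_units = 192,
                       learning_rate = 1e-3) {
  g <- default_model_grid()
  if (!embed_dim %in% g$embed_dim) stop_config("embed_dim outside grid")
  if (!lstm_units %in% g$lstm_units) stop_config("lstm_units outside grid")
  if (!dense_units %in% g$dense_units) stop_config("dense_units outside grid")
  if (!any(abs(learning_rate - g$learning_rate) < 1e-12)) {
    stop_config("learning_rate outside grid")
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 bidirectional = TRUE, trainable_embeddings = TRUE),
            class = "model_spec")
}

#' Build the token vocabulary from processed texts
#' @param texts list of character vectors (processed token sequences).
#' @param min_count minimum corpus frequency.
#' @return character vector, most frequent first.
#' @export
build_vocab <- function(texts, min_count = 1) {
  tab <- table(unlist(texts, use.names = FALSE))
  tab <- tab[tab >= min_count]
  names(sort(tab, decreasing = TRUE))
}

#' Encode token sequences as integer indices
#'
#' Tokens absent from `vocab` are dropped; sequences are truncated to
#' `maxlen` tokens (padding is handled internally by the model).
#' @param texts list of character vectors.
#' @param vocab from [build_vocab()].
#' @param maxlen maximum sequence length.
#' @return list of integer vectors (1-based indices into `vocab`).
#' @export
encode_sequences <- function(texts, vocab, maxlen = 256) {
  lapply(texts, function(tk) {
    idx <- match(tk, vocab)
    idx <- idx[!is.na(idx)]
    head(idx, maxlen)
  })
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the baseline text classifier
#'
#' Architecture: trainable embedding initialised from the pretrained word
#' vectors (out-of-vocabulary rows drawn from a seeded normal) -> BiLSTM
#' (`lstm_units` per direction; forward and backward final states
#' concatenated) -> dense ReLU (`dense_units`) -> dense sigmoid.
#'
#' @param spec a [model_spec()]; `embed_dim` must equal the word-vector
#'   dimension.
#' @param vocab character vector from [build_vocab()].
#' @param word_vectors matrix with words as rownames (see
#'   [gen_word_vectors()] / [read_word_vectors()]).
#' @param seed RNG seed for weight initialisation.
#' @return object of class `bilstm_model` (untrained).
#' @export
build_baseline <- function(spec, vocab, word_vectors, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (ncol(word_vectors) != spec$embed_dim) {
    stop("word-vector dimension does not match spec$embed_dim")
  }
  d <- spec$embed_dim; h <- spec$lstm_units; u <- spec$dense_units
  v <- length(vocab)
  params <- with_seed(seed, {
    e <- matrix(rnorm(v * d) / sqrt(d), v, d)
    hit <- vocab %in% rownames(word_vectors)
    e[hit, ] <- word_vectors[vocab[hit], , drop = FALSE]
    bf <- rep(0, 4 * h); bf[(h + 1):(2 * h)] <- 1   # forget-gate bias 1
    list(E = e,
         Wf = glorot(4 * h, d), Uf = glorot(4 * h, h), bf = bf,
         Wb = glorot(4 * h, d), Ub = glorot(4 * h, h), bb = bf,
         W1 = glorot(u, 2 * h), b1 = rep(0, u),
         W2 = glorot(1, u), b2 = 0)
  })
  structure(list(params = params, spec = spec, vocab = vocab,
                 trained = FALSE),
            class = "bilstm_model")
}

#' @exportS3Method base::print
print.bilstm_model <- function(x, ...) {
  cat(sprintf("bilstm_model (%s): embed %d, lstm %d/dir, dense %d, vocab %d\n",
              if (x$trained) "trained" else "untrained",
              x$spec$embed_dim, x$spec$lstm_units, x$spec$dense_units,
              length(x$vocab)))
  invisible(x)
}

#' Train the baseline classifier
#'
#' Adam on binary cross-entropy, batch size 32, one epoch by default.
#' Single-threaded and deterministic for a fixed seed.
#'
#' @param model from [build_baseline()].
#' @param seqs encoded sequences ([encode_sequences()]).
#' @param labels 0/1 vector.
#' @param epochs,batch_size training schedule.
#' @param seed shuffling seed.
#' @return the trained model.
#' @export
train_baseline <- function(model, seqs, labels, epochs = 1, batch_size = 32,
                           seed = 1) {
  stopifnot(inherits(model, "bilstm_model"), length(seqs) == length(labels))
  model$params <- .bilstm_train(model$params, seqs, as.numeric(labels),
                                model$spec$learning_rate,
                                as.integer(batch_size), as.integer(epochs),
                                as.integer(seed))
  model$trained <- TRUE
  model
}

#' Predict class probabilities
#' @param model a `bilstm_model` or `bilstm_extended`.
#' @param seqs encoded sequences.
#' @param features external feature matrix (extended model only).
#' @param batch_size forward-pass batch size.
#' @return numeric vector of probabilities in \[0,1\].
#' @export
predict_proba <- function(model, seqs, features = NULL, batch_size = 64) {
  if (inherits(model, "bilstm_extended")) {
    fw <- .bilstm_forward(model$base$params, seqs, as.integer(batch_size))
    stopifnot(!is.null(features), nrow(features) == length(seqs))
    ze <- features %*% t(model$We)
    ze <- sweep(ze, 2, model$be, "+")
    ae <- pmax(ze, 0)
    z2 <- (fw$dense + ae) %*% t(model$base$params$W2) +
      as.numeric(model$base$params$b2)
    as.numeric(1 / (1 + exp(-z2)))
  } else {
    .bilstm_forward(model$params, seqs, as.integer(batch_size))$prob
  }
}

#' Extend a trained baseline with an external-feature branch
#'
#' The external feature vector passes through a new dense ReLU layer with
#' the same number of units as the baseline's dense layer; its output is
#' added to the frozen baseline dense output before the shared sigmoid
#' output layer. Only the new layer is trainable. With the new branch at
#' zero the extended model reproduces the baseline exactly.
#'
#' @param model a trained `bilstm_model`.
#' @param feature_dim length of the external feature vector (> 0).
#' @param seed initialisation seed.
#' @param init `"glorot"` or `"zero"` initialisation of the new branch.
#' @return object of class `bilstm_extended`.
#' @export
extend_model <- function(model, feature_dim, seed = 1,
                         init = c("glorot", "zero")) {
  stopifnot(inherits(model, "bilstm_model"))
  init <- match.arg(init)
  if (feature_dim <= 0) stop("feature_dim must be positive")
  u <- model$spec$dense_units
  we <- if (init == "zero") matrix(0, u, feature_dim) else
    with_seed(seed, glorot(u, feature_dim))
  structure(list(base = model, We = we, be = rep(0, u),
                 feature_dim = as.integer(feature_dim), trained = FALSE),
            class = "bilstm_extended")
}

#' Train the extension branch (frozen base)
#'
#' Trains only the new dense layer with Adam at a fixed learning rate of
#' 1e-2; the baseline activations are precomputed once, so this is cheap.
#'
#' @param model a `bilstm_extended`.
#' @param seqs,labels training data (same order as `features`).
#' @param features external feature matrix.
#' @param lr fixed learning rate.
#' @param epochs,batch_size training schedule.
#' @param seed shuffling seed.
#' @return the trained extended model.
#' @export
train_extended <- function(model, seqs, features, labels, lr = 1e-2,
                           epochs = 1, batch_size = 32, seed = 1) {
  stopifnot(inherits(model, "bilstm_extended"))
  base <- model$base
  a1 <- .bilstm_forward(base$params, seqs, 64L)$dense     # n x U, frozen
  w2 <- as.numeric(base$params$W2)                        # U
  b2 <- as.numeric(base$params$b2)
  we <- model$We; be <- model$be
  m_w <- we * 0; v_w <- we * 0; m_b <- be * 0; v_b <- be * 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  n <- length(labels); step <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (off in seq(1, n, by = batch_size)) {
        idx <- ord[off:min(off + batch_size - 1, n)]
        f <- features[idx, , drop = FALSE]
        ze <- f %*% t(we)
        ze <- sweep(ze, 2, be, "+")
        ae <- pmax(ze, 0)
        z2 <- as.numeric((a1[idx, , drop = FALSE] + ae) %*% w2) + b2
        prob <- 1 / (1 + exp(-z2))
        dz2 <- (prob - labels[idx]) / length(idx)
        dae <- outer(dz2, w2)                   # B x U
        dze <- dae * (ze > 0)
        g_w <- t(dze) %*% f                     # U x F
        g_b <- colSums(dze)
        step <- step + 1
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        m_w <- beta1 * m_w + (1 - beta1) * g_w
        v_w <- beta2 * v_w + (1 - beta2) * g_w^2
        we <- we - lr * (m_w / bc1) / (sqrt(v_w / bc2) + eps)
        m_b <- beta1 * m_b + (1 - beta1) * g_b
        v_b <- beta2 * v_b + (1 - beta2) * g_b^2
        be <- be - lr * (m_b / bc1) / (sqrt(v_b / bc2) + eps)
      }
    }
  })
  model$We <- we
  model$be <- be
  model$trained <- TRUE
  model
}

#' Precision, recall and F1 at a threshold
#'
#' Predictions are `probability >= threshold`. `macro` averages the
#' per-class scores with equal weight (an absent class scores 0, with a
#' warning); `micro` pools all predictions and scores the positive class.
#'
#' @param probabilities numeric vector in \[0,1\].
#' @param labels 0/1 vector.
#' @param threshold decision threshold in (0,1).
#' @param average `"macro"` or `"micro"`.
#' @return list with `precision`, `recall`, `f1` and `per_class` (macro).
#' @export
evaluate <- function(probabilities, labels, threshold = 0.5,
                     average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(threshold > 0, threshold < 1)
  pred <- as.integer(probabilities >= threshold)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    warning("single-class label vector: per-class scores of the absent ",
            "class are set to 0")
  }
  prf <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    c(precision = pr, recall = rc, f1 = f1)
  }
  if (average == "micro") {
    s <- prf(1L)
    list(precision = s[["precision"]], recall = s[["recall"]],
         f1 = s[["f1"]], per_class = NULL)
  } else {
    per <- rbind(class0 = prf(0L), class1 = prf(1L))
    list(precision = mean(per[, "precision"]), recall = mean(per[, "recall"]),
         f1 = mean(per[, "f1"]), per_class = per)
  }
}

#' Stratified k-fold assignment
#' @param labels class labels.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return integer fold id (1..k) per observation; per-fold class counts
#'   differ by at most one from perfect stratification.
#' @export
stratified_kfold <- function(labels, k, seed = 1) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

sample_specs <- function(grid, n_trials, seed) {
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_trials <- min(n_trials, nrow(combos))
  pick <- with_seed(seed, sample.int(nrow(combos), n_trials))
  lapply(pick, function(i) do.call(model_spec, as.list(combos[i, ])))
}

bce_loss <- function(prob, labels) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Nested cross-validation of baseline and extended classifiers
#'
#' Stratified outer folds estimate generalisation; within each outer-train
#' split, a budgeted random search (or exhaustive search of a small grid)
#' over the hyperparameter grid is scored by mean validation
#' cross-entropy across stratified inner folds. The winning spec is
#' retrained on the full outer-train split as the baseline; the extension
#' branch is then trained on the same split at a fixed learning rate.
#' The inner search touches only outer-train documents; the ids it saw
#' are recorded per fold so leakage can be asserted.
#'
#' @param texts list of processed token sequences (one per document).
#' @param labels 0/1 vector.
#' @param features external feature matrix, rows aligned with `texts`.
#' @param word_vectors pretrained word-vector matrix.
#' @param grid hyperparameter grid (subset of [default_model_grid()]).
#' @param k_outer,k_inner fold counts (10 and 5 by default).
#' @param n_trials random-search budget per outer fold.
#' @param search `"random"` or `"exhaustive"`.
#' @param epochs,batch_size,maxlen training schedule.
#' @param thresholds named thresholds for the two models.
#' @param seed master seed; all derived seeds stay below 2^31.
#' @param keep_models keep the trained per-fold models (needed for
#'   external evaluation via [predict_ncv()]).
#' @param verbose print per-fold progress.
#' @return object of class `ncv_result`.
#' @export
nested_cv <- function(texts, labels, features, word_vectors,
                      grid = default_model_grid(), k_outer = 10, k_inner = 5,
                      n_trials = 10, search = c("random", "exhaustive"),
                      epochs = 1, batch_size = 32, maxlen = 256,
                      thresholds = c(baseline = 0.5, extended = 0.7),
                      seed = 1, keep_models = TRUE, verbose = FALSE) {
  search <- match.arg(search)
  n <- length(texts)
  stopifnot(length(labels) == n, nrow(features) == n)
  labels <- as.integer(labels)
  if (min(table(labels)) < k_outer) stop("a class has fewer members than k_outer")
  ids <- names(texts) %||% as.character(seq_len(n))
  outer_fold <- stratified_kfold(labels, k_outer, seed = seed)
  folds <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    test_ix <- which(outer_fold == f)
    train_ix <- which(outer_fold != f)
    vocab <- build_vocab(texts[train_ix])
    tr_seqs <- encode_sequences(texts[train_ix], vocab, maxlen)
    te_seqs <- encode_sequences(texts[test_ix], vocab, maxlen)
    tr_lab <- labels[train_ix]

    cand <- if (search == "exhaustive") {
      sample_specs(grid, .Machine$integer.max, seed + 7L * f)
    } else {
      sample_specs(grid, n_trials, seed + 7L * f)
    }
    inner_fold <- stratified_kfold(tr_lab, k_inner, seed = seed + 131L * f)
    losses <- vapply(seq_along(cand), function(ci) {
      mean(vapply(seq_len(k_inner), function(g) {
        fit_ix <- which(inner_fold != g)
        val_ix <- which(inner_fold == g)
        m <- build_baseline(cand[[ci]], vocab, word_vectors,
                            seed = seed + 1000L * f + 10L * ci + g)
        m <- train_baseline(m, tr_seqs[fit_ix], tr_lab[fit_ix],
                            epochs = epochs, batch_size = batch_size,
                            seed = seed + 1000L * f + 10L * ci + g)
        bce_loss(predict_proba(m, tr_seqs[val_ix]), tr_lab[val_ix])
      }, numeric(1)))
    }, numeric(1))
    win <- cand[[which.min(losses)]]

    base <- build_baseline(win, vocab, word_vectors, seed = seed + 17L * f)
    base <- train_baseline(base, tr_seqs, tr_lab, epochs = epochs,
                           batch_size = batch_size, seed = seed + 17L * f)
    ext <- extend_model(base, ncol(features), seed = seed + 23L * f)
    ext <- train_extended(ext, tr_seqs, features[train_ix, , drop = FALSE],
                          tr_lab, epochs = epochs, batch_size = batch_size,
                          seed = seed + 29L * f)

    p_base <- predict_proba(base, te_seqs)
    p_ext <- predict_proba(ext, te_seqs, features[test_ix, , drop = FALSE])
    te_lab <- labels[test_ix]
    folds[[f]] <- list(
      fold = f,
      test_ids = ids[test_ix],
      inner_ids = ids[train_ix],   # everything the inner search touched
      spec = win,
      inner_losses = losses,
      test_labels = te_lab,
      prob_baseline = p_base,
      prob_extended = p_ext,
      metrics = list(
        baseline = evaluate(p_base, te_lab, thresholds[["baseline"]], "macro"),
        extended = evaluate(p_ext, te_lab, thresholds[["extended"]], "macro")
      ),
      vocab = if (keep_models) vocab else NULL,
      baseline_model = if (keep_models) base else NULL,
      extended_model = if (keep_models) ext else NULL
    )
    if (verbose) {
      message(sprintf(
        "fold %d/%d: baseline F1 %.3f, extended F1 %.3f (lstm %d, dense %d)",
        f, k_outer, folds[[f]]$metrics$baseline$f1,
        folds[[f]]$metrics$extended$f1, win$lstm_units, win$dense_units))
    }
  }
  structure(list(folds = folds, thresholds = thresholds, k_outer = k_outer,
                 k_inner = k_inner, maxlen = maxlen, seed = seed),
            class = "ncv_result")
}

#' @exportS3Method base::print
print.ncv_result <- function(x, ...) {
  f1b <- vapply(x$folds, function(f) f$metrics$baseline$f1, numeric(1))
  f1e <- vapply(x$folds, function(f) f$metrics$extended$f1, numeric(1))
  cat(sprintf("ncv_result: %d outer x %d inner folds\n", x$k_outer, x$k_inner))
  cat(sprintf("  baseline macro F1 %.4f +/- %.4f (threshold %.2f)\n",
              mean(f1b), sd(f1b), x$thresholds[["baseline"]]))
  cat(sprintf("  extended macro F1 %.4f +/- %.4f (threshold %.2f)\n",
              mean(f1e), sd(f1e), x$thresholds[["extended"]]))
  invisible(x)
}

#' Evaluate the per-fold models on an external document set
#'
#' @param ncv an [nested_cv()] result with `keep_models = TRUE`.
#' @param texts,features external documents (processed token sequences and
#'   feature matrix).
#' @return list of per-fold lists with `prob_baseline`, `prob_extended`.
#' @export
predict_ncv <- function(ncv, texts, features) {
  stopifnot(inherits(ncv, "ncv_result"))
  lapply(ncv$folds, function(f) {
    if (is.null(f$baseline_model)) stop("models were not kept; rerun with keep_models = TRUE")
    seqs <- encode_sequences(texts, f$vocab, ncv$maxlen)
    list(prob_baseline = predict_proba(f$baseline_model, seqs),
         prob_extended = predict_proba(f$extended_model, seqs, features))
  })
}

#' Macro-F1 threshold sweep across outer folds
#'
#' @param ncv an `ncv_result`.
#' @param model `"baseline"` or `"extended"`.
#' @param lo,hi,step threshold grid.
#' @return data.frame `threshold`, `mean_f1`, `sd_f1` plus the per-fold
#'   matrix in `attr(, "per_fold")`.
#' @export
threshold_sweep <- function(ncv, model = c("extended", "baseline"),
                            lo = 0.5, hi = 0.95, step = 0.05) {
  model <- match.arg(model)
  key <- if (model == "baseline") "prob_baseline" else "prob_extended"
  ths <- seq(lo, hi, by = step)
  per_fold <- sapply(ncv$folds, function(f) {
    vapply(ths, function(t)
      evaluate(f[[key]], f$test_labels, t, "macro")$f1, numeric(1))
  })
  per_fold <- matrix(per_fold, nrow = length(ths))
  out <- data.frame(threshold = ths,
                    mean_f1 = rowMeans(per_fold),
                    sd_f1 = apply(per_fold, 1, sd))
  attr(out, "per_fold") <- per_fold
  out
}
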
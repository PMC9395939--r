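# dialogi

Triage of drug-induced liver injury (DILI) literature by combining text
with chemical and disease similarity.

DILI is a rare but severe adverse drug reaction, and the published case
reports and experimental studies that document it remain the main source
of evidence for both clinicians and drug developers. Finding the
DILI-relevant papers is hard: the condition is multifactorial and its
clinical presentation mimics other liver diseases, so purely lexical
classifiers miss papers that discuss *similar* drugs or *similar*
diseases in unfamiliar words. `dialogi` addresses this by learning
concept embeddings for diseases and chemicals from ontology and
association data — a context in which "similar" is meaningful — and
feeding them, alongside the text, to a neural classifier.

## What the package does

1. **Text processing** (`preprocess()`, `parse_pubtator()`, `align()`,
   `export_processed()`): titles and abstracts are tokenised and
   lemmatised through a pluggable backend, filtered to
   nouns/verbs/adjectives/adverbs with lemma length ≥ 3 and no
   stopwords. Externally supplied chemical/disease annotations
   (PubTator format, 0-based half-open offsets over
   `title + " " + abstract`) are aligned to kept tokens when they cover
   ≥ 90% of the mention span, and per-text relative frequencies
   `f_c = n_c / Σ_c' n_c'` are computed per category.
2. **Concept embeddings** (`tfidf()`, `reduce_svd()`,
   `empirical_null()`, `build_network()`, `node2vec_embed()`): a term
   hierarchy (each tree number contributes its path prefixes as words)
   or a bipartite association table (partners as words) becomes a
   corpus; TF-IDF weights (`tf · (ln(n/df) + 1)`, df filters `[5, 80%]`)
   are reduced by truncated SVD to ~90% explained variance; each term's
   100 nearest cosine neighbours form a network with edge weights
   `−log10 p`, where `p` is an empirical p-value against 100,000
   randomly sampled term-pair cosines; edges with weight ≤ 2 are pruned
   except each term's 3 nearest; node2vec (p = q = 1, 10×80 walks,
   window 10, 5 negatives) yields 128-dimensional vectors.
3. **Space comparison** (`rbo()`, `cca_pearson()`,
   `compare_spaces()`): extrapolated rank-biased overlap (p = 0.7) of
   depth-100 neighbour lists, averaged over common terms, and the mean
   Pearson correlation of the first three canonical variable pairs.
4. **External feature vectors** (`compose_space()`, `text_vector()`,
   `batch_featurize()`): member spaces are concatenated (no centring or
   scaling) and SVD-reduced group-wise — the reference profile is
   103 + 47 = 150 disease and 265 + 35 = 300 chemical dimensions — then
   each document receives `v = [v_dis/‖v_dis‖ ; v_chem/‖v_chem‖]` with
   `v_cat = Σ_c f_c e_c` (missing concepts contribute zero vectors).
5. **Classifiers** (`build_baseline()`, `extend_model()`,
   `nested_cv()`): the baseline is a trainable embedding (pretrained
   init) → BiLSTM → dense ReLU → sigmoid, trained one epoch with Adam at
   batch 32. The extended model adds a dense ReLU branch over the
   feature vector whose output is added to the frozen baseline dense
   output before the shared sigmoid; only that branch is trained
   (lr 10⁻²). Both are tuned/evaluated under nested cross-validation
   (10 outer × 5 inner folds, stratified) with thresholds 0.5 (baseline)
   and 0.7 (extended), plus `threshold_sweep()`.
6. **Exploration** (`project()`, `query()`, `explain_hit()`):
   unit-normalise → PCA(15) → 3D t-SNE, and cosine-ranked retrieval of
   documents against a weighted concept query.
7. **Synthetic data** (`gen_documents()` and friends): every input the
   pipeline needs — documents with planted lexical/concept signal, exact
   PubTator annotations, a random hierarchy, block-structured
   association tables, random word vectors — generated deterministically
   from a seed, so the whole pipeline is testable offline.

The BiLSTM, node2vec trainer and t-SNE are implemented in-package
(RcppArmadillo / R): no deep-learning framework is required.

## Worked example

```r
library(dialogi)

## 1. a synthetic two-class corpus with planted lexical + concept signal
corp <- gen_documents(synth_config(n_docs = 600, signal_strength = 0.8, seed = 1))
docs <- annotate_corpus(corp$documents, gen_annotations(corp))

## 2. disease/chemical concept embeddings from block-structured associations
dis <- corp$concepts[corp$concepts$category == "disease", ]
chm <- corp$concepts[corp$concepts$category == "chemical", ]
assoc_d <- gen_association_tables(nrow(dis), 400, within_p = 0.6, between_p = 0.05,
                                  seed = 2, term_ids = dis$concept_id, blocks = dis$block)
assoc_c <- gen_association_tables(nrow(chm), 400, within_p = 0.6, between_p = 0.05,
                                  seed = 3, term_ids = chm$concept_id, blocks = chm$block)
disease_space  <- embed_concepts(corpus_from_associations(assoc_d$tables$genes),
                                 dim = 32, seed = 4, n_pairs = 50000, n_neighbors = 50)
chemical_space <- embed_concepts(corpus_from_associations(assoc_c$tables$genes),
                                 dim = 32, seed = 5, n_pairs = 50000, n_neighbors = 50)
nn_purity(disease_space, assoc_d$blocks)
#> block recovery (1-NN purity): 1.00

## 3. per-document external feature vectors
fz <- batch_featurize(docs, disease_space, chemical_space)
fz$coverage
#>   class   disease  chemical   n
#> 1     0 0.7966667 0.7966667 300
#> 2     1 0.8033333 0.8033333 300

## 4. baseline vs extended classifier (one split; nested_cv() for the full CV)
texts <- lapply(docs, function(d) export_processed(d, "replace_id"))
vocab <- build_vocab(texts)
wv <- gen_word_vectors(vocab, dim = 50, seed = 6)
seqs <- encode_sequences(texts, vocab, maxlen = 64)
y <- corp$documents$label
tr <- 1:450; te <- 451:600
base <- train_baseline(build_baseline(model_spec(50, 32, 192, 1e-2), vocab, wv, seed = 7),
                       seqs[tr], y[tr], seed = 7)
ext <- train_extended(extend_model(base, ncol(fz$features), seed = 8),
                      seqs[tr], fz$features[tr, ], y[tr], seed = 9)
evaluate(predict_proba(base, seqs[te]), y[te], 0.5, "macro")$f1
#> baseline macro F1 @0.5: 0.987
evaluate(predict_proba(ext, seqs[te], fz$features[te, ]), y[te], 0.7, "macro")$f1
#> extended macro F1 @0.7: 0.980

## 5. retrieval: rank documents against a concept query
q <- query(data.frame(concept_id = dis$concept_id[1:2], category = "disease",
                      weight = c(0.7, 0.3)),
           disease_space, chemical_space, fz$features, top = 3)
q$ranking
#>       doc_id similarity
#> 10579  10579  0.6732237
#> 10451  10451  0.6693227
#> 10161  10161  0.6619005
```

The 80% per-class coverage reflects the generator's default 20%
unannotated documents (those receive zero feature vectors and exercise
the fallback path); the 1-NN purity of 1.00 shows the embedding pipeline
recovered the four planted association blocks; and the two F1 scores
show both classifiers near ceiling when lexical signal is strong — the
extended model's advantage appears under distribution shift, which the
acceptance suite measures.

## Command line

```sh
Rscript inst/cli/dialogi.R preprocess --docs docs.tsv \
    --annotations anns.pubtator --mode replace_id --out processed.tsv
Rscript inst/cli/dialogi.R embed-concepts --source association \
    --in assoc.tsv --out space.vec --dim 128 --seed 1
Rscript inst/cli/dialogi.R compare-spaces --a a.vec --b b.vec --out cmp.json
Rscript inst/cli/dialogi.R train --docs processed.tsv --features features.tsv \
    --vectors words.vec --outer 10 --inner 5 --seed 1 --out runs/
```

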
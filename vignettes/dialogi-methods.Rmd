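---
title: "Methods: concept-embedding-augmented classification of DILI literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept-embedding-augmented classification of DILI literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Drug-induced liver injury (DILI) literature triage is a binary text
classification problem with a twist: the relevant signal is often not
lexical but *conceptual*. Two papers may discuss different drugs and
different liver conditions in different vocabulary and still belong to
the same class because the drugs behave similarly and the diseases are
related. Word embeddings trained on free text do not capture this — the
free-text context of a drug name encodes how people write about drugs,
not what drugs do. `dialogi` therefore learns disease and chemical
embeddings from data in which similarity *is* the structure (ontology
hierarchies and curated association tables), summarises each document's
annotated concepts as an external feature vector, and trains two neural
classifiers: a text-only baseline and an extended model that also sees
the features.

## Concept embedding learning

Each data source becomes a corpus. A hierarchy contributes, for every
term's dot-delimited tree number `c1.c2.….cn`, the `n` path prefixes as
words, pooled across the term's tree numbers with multiplicity — terms
sharing a deep prefix share many words. An association table contributes
each term's multiset of interaction partners.

The corpus is TF-IDF weighted. The dialect is deliberately pinned
because sources rarely state it: binary document frequency, words kept
when `5 ≤ df ≤ 0.8·n_terms` (filtered *before* weighting), `tf` the raw
count, `idf = ln(n_terms/df) + 1`, no length normalisation. Terms whose
vector becomes all-zero are purged. Oracle tests freeze this dialect
exactly, so any change is a deliberate, visible decision.

Truncated SVD keeps the smallest k whose cumulative squared-singular-value
share reaches the target (default 0.9) on the uncentred matrix. A
similarity network is then built: each term's 100 highest-cosine
neighbours are candidate edges; weights are `−log10 p` with `p` an
empirical p-value of the cosine against 100,000 sampled distinct term
pairs. We smooth with `p = (r+1)/(N+1)` — the source material is silent
here, and the unsmoothed estimate would yield `p = 0` and infinite
weights for any cosine above the sample maximum. Edges with weight ≤ 2
are pruned except that every term keeps its 3 nearest neighbours (taken
from the original cosine ranking, not recomputed after pruning); an edge
survives if either endpoint demands it. Cosine ties break by ascending
term id so that the network is a pure function of the space.

node2vec runs on this weighted graph with the canonical defaults
(`p = q = 1`, 10 walks of length 80 per node, window 10, 5 negative
samples, 1 epoch, initial learning rate 0.025, unigram^0.75 noise
distribution); training is single-threaded with an explicit RNG, so a
seed pins the matrix bit-for-bit. The walk sampler implements the full
second-order bias and reduces to weighted first-order walks at
`p = q = 1`.

## Space comparison

Rank-biased overlap uses the extrapolated point estimate on depth-100
cosine neighbour lists (query excluded, lists restricted to the common
terms *before* ranking, which guarantees conjoint universes; the
alternative — restricting after — was the open choice). Persistence
`p = 0.7` makes the measure top-weighted. The implementation's closed
form is checked against an independent brute-force series summation to
1e-12.

The CCA route fits canonical correlations on the common-term rows and
averages the in-sample Pearson correlations of the first three pairs.
Because synthetic tests routinely have fewer terms than dimensions, both
covariance blocks carry a small ridge (1e-3); self- and
rotated-self-comparisons still score exactly 1, which the tests assert.

## External feature vectors

Member spaces are aligned on the union of their terms (missing terms are
zero rows; nothing is centred or scaled), concatenated within groups,
SVD-reduced per group (a target below 1 is a variance fraction, 1 or
more an exact dimension), and concatenated. The reference profile
reduces the association-based disease group to 103 dimensions plus 47
hierarchy dimensions (150 total) and the chemical signature group to
265 + 35 = 300; `paper_profile()` records these targets.

A document's vector is, per category, the relative-frequency-weighted
average of its concepts' embeddings, unit-normalised unless exactly
zero, concatenated disease-first. Three deliberate choices: frequencies
are computed per category, not jointly (the open question — per-category
keeps the two halves independently interpretable); missing concepts
contribute zero vectors *without* redistributing their weight (so a
document dominated by unknown concepts gets a short pre-normalisation
vector rather than a confident wrong one); and the coverage flags record
annotation presence, not vector presence, so "annotated but unknown" is
distinguishable from "unannotated".

## Classifiers and validation

The baseline is: trainable embedding initialised from pretrained word
vectors (out-of-vocabulary rows ~ N(0, 1/√d)), a BiLSTM whose forward
and backward final states are concatenated, a dense ReLU layer, and a
sigmoid output. The tuned grids are embedding dimension
{50, 100, 200, 300}, LSTM units 32–96 step 16 (per direction), dense
units 192–320 step 32, learning rate {1e-3, 5e-3, 7e-3, 1e-2}. Training
is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7) on binary cross-entropy, batch
32, one epoch — the models overfit quickly, and at one epoch
regularisation buys nothing, so none is applied. Weights use Glorot
uniform initialisation with forget-gate bias 1; sequences are truncated
to a configurable length (default 256) and padding is masked by carrying
LSTM state through padded steps. Because no deep-learning framework is
available in the target environment, the forward/backward passes are
implemented directly (RcppArmadillo), batched, single-threaded and
seeded — two builds and trainings with one seed are identical, which the
tests assert.

The extended model feeds the external feature vector through a new dense
ReLU layer with the same unit count as the baseline's dense layer and
adds the two dense outputs before the shared (frozen) sigmoid layer.
Only the new layer trains, at a fixed learning rate of 1e-2. This design
adds no new hyperparameters, and setting the new branch to zero
reproduces the baseline's probabilities exactly — the identity the
acceptance suite checks to 1e-6.

Nested cross-validation uses 10 stratified outer folds; within each
outer-train split, a seeded random search (budget configurable, default
10; exhaustive mode for tiny grids) is scored by mean validation
cross-entropy over 5 stratified inner folds. The winner retrains on the
full outer-train split, the extension trains on top, and per-document
probabilities are recorded for the outer test fold. The vocabulary is
rebuilt from each outer-train split so the inner search can never see a
test document even through token statistics; each fold records the id
sets it touched, and the acceptance suite asserts their disjointness.
Thresholds are fixed at 0.5 (baseline) and 0.7 (extended) — "about 0.7"
pinned to 0.7 exactly — with `threshold_sweep()` provided for
re-tuning. "Micro" F1 is pooled positive-class F1; the alternative
(micro over both classes) degenerates to accuracy and contradicts the
contract's own worked example.

## The synthetic world

The generator states one world and the tests live in it:

* 2,000 documents, balanced classes; abstracts of ~150 background tokens
  (vocabulary 5,000, Zipf-weighted, 15% function words) — corpus-scale
  statistics the source never reports, so these are fixed once as
  plausible for abstracts and exposed in `synth_config()`.
* 12 discriminative lexical tokens per class, emitted with probability
  `signal_strength` (default 0.8) in their class and `noise_rate`
  (default 0.05) in the other.
* 100 disease + 100 chemical MeSH-style descriptors in 4 ground-truth
  blocks (IDs share the D-prefix; only the category label distinguishes
  them, forcing downstream code not to parse IDs). 8 discriminative
  concepts per class and category, drawn from disjoint block halves so
  block recovery translates into class signal; emission probability
  `concept_signal`.
* 20% of documents receive no annotations, exercising the zero-vector
  fallback; annotation offsets are exact by construction.
* Association tables link a term to a partner with probability 0.6
  within a block and 0.05 across — rates at which the blocks are
  recoverable but not trivially (1-NN purity ≈ 0.95–1.0, not 1.0 by
  construction).

What the generator does *not* emulate: grammar and discourse (documents
are bags of tokens, so the BiLSTM's sequence modelling is exercised only
mechanically), annotator errors other than missingness, realistic MeSH
tree shapes, and correlated association tables. A green classification
test therefore establishes that the pipeline's plumbing, bookkeeping and
optimisation work and that concept features carry class signal when
planted — not that the architecture outperforms alternatives on real
prose.

The distribution-shift experiment mirrors the generalisation comparison:
train on a corpus with lexical signal 0.55 and concept signal 0.9, then
evaluate on a set generated from the *same* planted-concept manifest
with lexical signal at the noise floor. The baseline degrades; the
extended model, reading concept embeddings that generalise across
same-block concepts, wins in ≥ 8 of 10 folds.

## Numerical choices and degenerate inputs

* Empirical p-values: add-one smoothing as above; `pvalue()` is
  non-increasing in the cosine by construction.
* Zero-norm vectors are excluded from null sampling (with a warning) and
  stay zero under normalisation; a rank-deficient matrix that cannot
  reach the variance target returns full rank with a warning.
* Mentions failing token alignment still count toward relative
  frequencies (annotation existence does not depend on the lemma
  filter); they are only excluded from text replacement. Overlapping
  mentions resolve to the longer, then earlier, mention.
* The offset convention is everywhere 0-based, half-open over
  `title + " " + abstract`; the PubTator reader tolerates the newline
  dialect (the separator is one character either way).
* t-SNE (implemented exactly, O(n²)) uses perplexity 30 capped at
  (n−1)/3, 12× early exaggeration for 50 iterations, momentum 0.5→0.8;
  inputs are unit-normalised first so euclidean distances are monotone
  in cosine distances, then PCA-reduced to 15 components.
* Search-budget scaling: acceptance runs use a trial budget of 2 over a
  reduced grid and 64-token truncation to fit one CPU; the stated world
  (corpus size, folds, epoch, batch, signal levels, thresholds) is never
  scaled.

## Known limitations

The lemmatizer shipped is a deterministic fixture (identity lemma,
lexicon POS) — adequate for the synthetic vocabulary, not for real
prose; a model-backed lemmatizer can be plugged in through the same
interface. Neighbour search is exact (dense cosine matrix), fine at desk
scale, quadratic in terms. The BiLSTM implementation is single-threaded
by design for reproducibility; it is fast enough for the stated corpus
sizes but is not a GPU framework. Chemical structure-based signatures
are accepted as precomputed input spaces only; resolving identifiers to
structures is out of scope.
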
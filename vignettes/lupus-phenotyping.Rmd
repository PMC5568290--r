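---
title: "Phenotyping SLE from clinical notes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping SLE from clinical notes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Identifying which patients in an electronic health record (EHR) carry a
phenotype such as systemic lupus erythematosus (SLE) from free-text
clinical notes is a classification task: each patient contributes many
notes, only some of which are relevant, and the reference label comes from
clinical classification criteria rather than from any single sentence.
`lupusnlp` implements that task end to end — a synthetic note generator
with rule-based ground truth, two classical feature routes (bag-of-words
and dictionary concepts with negation), five classifier families, and the
evaluation machinery (repeated cross-validation, external test,
permutation null) needed to compare them honestly.

Real rheumatology EHR corpora are protected and cannot ship with a
package. The synthetic generator is therefore a first-class module: it
emulates the statistical structure the analysis depends on, so every
pipeline property can be exercised and tested without access to protected
data. What passing those tests shows — and does not show — about real
notes is discussed at the end.

# Ground truth: the ACR/SLICC rule

A patient profile records which of the eleven ACR classification criteria
are met (malar rash, discoid rash, photosensitivity, oral ulcers,
nonerosive arthritis, serositis, renal disorder, neurologic disorder,
hematologic disorder, immunologic disorder, positive ANA) plus two flags
for the SLICC alternative pathway. The label rule is

> SLE iff (number of criteria met) >= 4, or biopsy-proven lupus
> nephritis is present together with ANA or anti-dsDNA antibodies.

`label_from_criteria()` implements this literally, and the test suite
checks it against an exhaustive truth-table evaluation over all
2^11 criterion subsets and flag combinations. Nephritis implies renal
disorder (criterion 7); profiles violating that implication are rejected
at construction.

# The synthetic corpus generator

`synth_config()` fixes the study conditions. Defaults mirror the shape of
the rheumatology cohort the pipeline is designed around: 662 patients,
48.6% SLE (322/662), a 100-patient external holdout, and ICD-9 code 710.0
assigned with 90% sensitivity and specificity — which places the
rule-based ICD-9 baseline near 90% accuracy and 0.90 AUC on balanced
data, the error level the baseline is expected to show.

Each patient receives 4–12 notes (the real per-patient note-count
distribution is not public; this range is an arbitrary but fixed choice).
A configurable fraction of notes contain the substring `"rheumatol"` and
carry the signal: each held criterion is mentioned with probability
`criterion_mention_rate` using phrases from a fixed criterion lexicon.
Nuisance structure is injected at configurable rates:

* **Negation** — a `negated_mention_rate` share of mentions are wrapped
  in templates such as "no evidence of X" or "denies X", and notes may
  negate criteria the patient does *not* have.
* **Ambiguity** — the token "SLE" appears both as a lupus mention (in
  cases) and in an unrelated arbovirus context (in controls), mirroring
  the St. Louis Encephalitis confusion of dictionary concept extraction;
  "ER" likewise (emergency room vs. endoplasmic reticulum).
* **Artifacts** — site-specific tokens (de-identification residue,
  author ids) appear at a class-skewed rate, reproducing the confounder
  that real bag-of-words features are prone to pick up.

With all nuisance rates at zero, the class-discriminative tokens are
exactly the criterion lexicon phrases — a property the tests assert.
The generator is deterministic: a config (including its mandatory seed)
yields a byte-identical cohort.

What the generator does **not** emulate: clinically realistic language,
temporal structure, note-type semantics, inter-annotator noise in the
gold standard, and the long-tailed vocabulary of real notes. High
synthetic AUCs therefore validate the machinery, not clinical
performance.

# Corpus preparation

The fixed order of operations is filter → holdout split → bootstrap
balancing (`prepare_cohort()`). Whether balancing preceded or followed
the holdout in the original study design is not recoverable from its
description; the order here is declared, not inferred. Filtering keeps
notes whose case-folded text contains `"rheumatol"` (case-insensitive
substring — clinical text capitalisation is unreliable); patients left
with no notes go to an exclusion log rather than vanishing. Balancing
resamples the minority class with replacement, suffixing duplicate ids;
duplicates never straddle the TRAIN/TEST boundary, and the CV harness
assigns duplicates to the same fold as their source — two leakage guards
the method description does not discuss but that the resampling design
requires.

# Feature routes

**Bag-of-words.** Punctuation stripping, case folding, stop-word removal,
Porter2 stemming, term counts, L1 row normalisation. The stemmer is a
from-scratch implementation of the published Porter2 (Snowball English)
algorithm, verified against frozen reference outputs. Digit tokens are
kept as-is (numeric stems are legitimate features). The shipped stop list
deliberately keeps negators: the classical illustration that "patient
does not have lupus" increments both `lupus` and `not` — the malformation
concept features are meant to fix — must remain reproducible. This is a
declared resolution of a genuine tension (stop-word removal vs. counting
"not"); the stop list is fixed and versioned in code. Stems occurring in
fewer than 2 training documents are dropped to control matrix width.

**Concept dictionary.** A shipped dictionary of synthetic concept ids
with lower-cased surface forms stands in for a licensed UMLS subset; no
cTAKES/YTEX pipeline is run. Matching is longest-first, leftmost-first
over sentence tokens ("lupus nephritis" consumes its span so plain
"lupus" is not also counted). A match increments every concept its form
maps to — ambiguous forms double-count by design, reproducing the CUI
ambiguity failure mode. A mention is decremented instead when a negation
cue occurs in the same sentence at most W = 5 tokens before it; 5 is the
classic NegEx-style window, a declared default (the original concept
pipeline delegated negation to its extraction system without stating
parameters).

**Normalisation and selection.** Both matrices are L1 row-normalised
(which flavour of normalisation the study used is unstated; relative
term frequency is the conventional choice for count features). Features
are then ranked by mean Gini impurity decrease in a 300-tree randomized
ensemble and the top 100 retained, with lexicographic tie-breaks for
determinism. Selection is refit inside every CV fold's training portion.

# Classifiers

All families sit behind one contract: `fit_classifier(spec, matrix,
labels)` → `predict()` → `(patient_id, label, score)` with score =
P(SLE) in [0, 1] and the label thresholded at 0.5.

* **ICD-9 rule** — score 1 iff code 710.0 present; no training. A hard
  0/1 rule has AUC = (sensitivity + specificity)/2 = accuracy on balanced
  data, an identity the tests assert to 1e-12.
* **Naive Bayes** — multinomial with Laplace smoothing on raw counts;
  Gaussian when inputs can be negative (concept matrices after negation
  decrements) or are non-integer. The variant is recorded in the model.
* **Linear SVM** — decision values mapped through a rank-preserving
  sigmoid so a graded score exists for ROC analysis (how graded scores
  were obtained in the original evaluation is unstated; this choice is
  explicit and leaves the AUC of the decision values unchanged).
* **Random forest** — 300 probability trees (ranger), vote-fraction
  scores.
* **Shallow neural network** — one hidden layer of 250 nodes (nnet),
  logistic hidden units, cross-entropy loss, weight decay 1e-3, at most
  200 iterations. nnet is the canonical single-hidden-layer
  implementation in R; it offers neither rectified units nor early
  stopping, so regularisation is by weight decay — the study's stated
  architecture (one layer, 250 nodes) is respected, its unstated training
  details are these declared defaults. Deeper architectures are out of
  scope (they were found not viable) and requesting more than one hidden
  layer is an error.

# The inversion classifier

The core method scores *documents* with *language models*. A base
skip-gram embedding is trained on all training sentences; one copy per
class is then fine-tuned on that class's sentences only, yielding two
highly specialised models over a shared vocabulary and Huffman tree.
For a sentence s = w_1..w_T, the log-likelihood under class k's model is

    l_k(s) = sum_t sum_{1 <= |j| <= c} log P_k(w_{t+j} | w_t)

with each conditional computed exactly through the hierarchical-softmax
path product of sigmoids. Hierarchical softmax is mandatory here —
negative sampling does not define a tractable exact likelihood. Training
is single-threaded with an internal seeded RNG so a seed determines the
model bit-for-bit; the C++ scorer is checked against a scalar R oracle to
1e-9.

Defaults follow the study settings: d = 500 dimensions, context window
c = 5, minimum count 20. The phrase "minimum sentence word count of 20"
is ambiguous between a vocabulary frequency threshold and a sentence
length filter; it is read here as the frequency threshold (the standard
embedding parameter), and a literal sentence-length filter is available
as `min_sentence_length` for anyone preferring the other reading.

Classification: each sentence is assigned to argmax_k of l_k/n_pairs +
log pi_k, where n_pairs is the number of scored skip-gram pairs (length
normalisation makes the sentence decision length-invariant; raw
likelihoods are available via `normalize_ll = FALSE`) and pi_k are the
class priors (empirical training frequencies — 0.5 after balancing).
The patient label is the majority vote over sentence labels, the study's
stated rule; summed-likelihood aggregation is provided as a labelled
alternative (`aggregate = "sumll"`). Ties — between sentence classes or
in an even patient vote — are broken by the larger total log-likelihood
margin. The patient score for ROC purposes is the fraction of sentences
voting SLE. Sentences with fewer than two in-vocabulary tokens are
unscoreable and excluded from voting; a patient with no scoreable
sentence abstains at score 0.5.

The benchmark suite exercises this route at d = 50 on planted-signal
corpora (disjoint class vocabularies mentioned in 30% of sentences),
training on 200 patients and scoring patient-level AUC on 200 held-out
patients — a scale at which the whole check runs in minutes while still
separating signal (AUC ≥ 0.9) from null corpora (AUC ≈ 0.5).

# Evaluation machinery

`auc()` is the Mann–Whitney rank statistic with ties counted 1/2,
cross-checked in tests against brute-force pair counting and an
independent implementation (pROC). `run_cv()` performs stratified k-fold
cross-validation (default 5-fold, 20 repeats) with the entire pipeline
refit per fold; accuracy is reported on the 0–100 scale and AUC on 0–1.
Confidence intervals use the empirical distribution of the repeat-level
means with a normal approximation — a simpler estimator than
influence-function cvAUC machinery with the same target, and the method
name is stamped into every report. External-test metrics come from a
pipeline refit on all training patients.

`permutation_test()` builds the null: for each of (default) 200
permutations the labels are scrambled, the pipeline is refit, and its AUC
against the permuted labels is measured on held-out folds. The
per-permutation AUC is the *mean of fold-level AUCs* rather than an AUC
of pooled out-of-fold scores: a fold-level AUC is an exact rank statistic
on untouched data and is centred at 1/2 under label permutation, whereas
pooling scores across differently-fitted fold models mixes calibrations
and can bias the pooled statistic slightly below 1/2. The permutation
count is configurable and recorded; both mean-based confidence intervals
(95% and 99%) and sample quantiles are reported.

# Problem sizes used by the shipped checks

The test-suite and acceptance-script problem sizes are the package's own
benchmark choices: permutation null on a 300-patient balanced cohort with
100 bag-of-words features and 200 permutations; inversion benchmarks at
d = 50 with 200 patients and 5 seeds; feature-selection recovery at 200
rows, 100 features, 50 seeds; AUC oracle on 1000 random instances of
n ≤ 30. Embedding-dimension scaling (50 vs. 500) changes training cost,
not the logic under test; the full-size configuration remains the
default for analyses.

# Known limitations

* The generator's language is template-based; results on it bound only
  the machinery, not clinical accuracy.
* The concept dictionary is a small synthetic stand-in; real UMLS
  coverage and its failure modes are far broader.
* nnet's training (logistic units, weight decay) differs from modern MLP
  practice; with 100 input features this is of little consequence, but
  the family is not a general deep-learning surrogate.
* Document zoning, lab-value feature engineering and word-vector
  averaging are deliberately out of scope.
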
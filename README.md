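# lupusnlp

Phenotyping systemic lupus erythematosus (SLE) from free-text clinical
notes: a complete, tested R pipeline for clinical-NLP researchers who want
to compare classical text classifiers with classification by **Bayesian
inversion of distributed language models** — and to do so reproducibly,
without access to protected EHR data.

## What it does

Real rheumatology note corpora are IRB-protected, so the package ships a
first-class **synthetic EHR generator**: per-patient multi-note corpora
with ACR/SLICC rule-based ground truth (SLE iff ≥ 4 of the 11 ACR
criteria, or lupus nephritis with ANA/anti-dsDNA), class-correlated
criterion vocabulary, negated mentions, ambiguous abbreviations ("SLE" as
lupus vs. St. Louis Encephalitis, "ER" as emergency room vs. endoplasmic
reticulum), site-artifact tokens, and ICD-9 code 710.0 assigned with
configurable sensitivity/specificity.

On top of it:

* **Corpus preparation** — notes filtered by the stem `"rheumatol"`,
  aggregated into patient-centric documents, a 100-patient external
  holdout, and bootstrap class balancing with leakage guards.
* **Features** — bag-of-words (punctuation stripping, stop words, Porter2
  stemming, L1 normalisation) and negation-aware dictionary concept
  counts (a mention within 5 tokens of a cue like "no"/"denies" counts
  −1), reduced to the top 100 features by Gini importance in a 300-tree
  ensemble.
* **Classifiers** — ICD-9 rule baseline, naive Bayes, linear-kernel SVM,
  300-tree random forest and a shallow 1×250 neural network behind one
  `fit`/`predict` contract.
* **Word2Vec inversion** — a base skip-gram model with hierarchical
  softmax (exact sentence likelihoods), fine-tuned once per class; a
  sentence `s` scores `ℓ_k(s) = Σ_t Σ_{1≤|j|≤c} log P_k(w_{t+j} | w_t)`
  under class `k`, sentences vote by `argmax_k ℓ_k/n + log π_k`, and the
  patient label is the majority vote. Implemented in Rcpp, single-threaded
  and bit-reproducible; defaults d = 500, window 5, min count 20.
* **Evaluation** — Mann–Whitney AUC, 5-fold CV repeated 20 times with the
  whole pipeline (including feature selection) refit inside each fold,
  95% CIs, external-test scoring with ROC export, and a label-permutation
  null test whose mean AUC sits at 0.500.

## Worked example

```r
library(lupusnlp)

cohort <- generate_cohort(synth_config(n_patients = 300, holdout = 60, seed = 5))
cohort <- prepare_cohort(cohort)   # filter -> holdout split -> balance
cohort
#> <pheno_cohort> 334 patients (167 SLE / 167 CONTROL), 1122 notes
#>   split: 268 TRAIN / 66 TEST

pl <- pheno_pipeline(classifier_spec("random_forest"), features = "bow")
run_cv(pl, cohort, cv_scheme(k = 5, repeats = 5, seed = 1))
#> <eval_report> 5x5-fold CV
#>   CV accuracy: 83.781% [83.132, 84.430]
#>   CV AUC: 0.918 [0.913, 0.923]  (CI: normal approximation over repeat-level means)

test <- evaluate_test(fit_pipeline(pl, cohort), cohort)
#> external test: accuracy 90.91%, AUC 0.977

inv <- pheno_pipeline("w2v_inversion",
                      embedding = embedding_config(dimension = 50,
                                                   min_count = 10, seed = 4))
evaluate_test(fit_pipeline(inv, cohort), cohort)
#> inversion test: accuracy 83.33%, AUC 0.874

evaluate_test(fit_pipeline(pheno_pipeline(classifier_spec("icd9_rule")), cohort), cohort)
#> ICD-9 baseline: accuracy 84.85%, AUC 0.848
```

Reading the numbers: the bag-of-words random forest separates cases from
controls well above the ICD-9 billing-code baseline, whose accuracy and
AUC coincide (a hard 0/1 rule has no graded score, so on balanced data
AUC = accuracy/100 exactly). The inversion classifier — run here at a
reduced embedding dimension of 50 — lands near the baseline, consistent
with its behaviour as a feature-free method. Exact values depend only on
the seeds shown.

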
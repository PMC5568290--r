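# Evaluation harness: rank-based AUC, repeated stratified k-fold
# cross-validation with per-fold refitting of the whole pipeline (feature
# construction, normalisation and Gini selection are fitted on each fold's
# training portion only), external-test scoring with ROC export, and the
# label-permutation null.

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with ties counted one half: the
#' probability that a uniformly chosen SLE patient outscores a uniformly
#' chosen control. Identical to the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores Numeric scores, higher = more SLE-like.
#' @param labels `"SLE"`/`"CONTROL"` (or logical/0-1 with `TRUE`/1 = SLE)
#'   aligned with `scores`.
#' @return AUC in [0, 1].
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c("SLE", "CONTROL", "SLE", "CONTROL"))
#' @export
auc <- function(scores, labels) {
  pos <- to_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

to_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "SLE"
}

#' Empirical ROC points
#'
#' (FPR, TPR) at every distinct score threshold, ties grouped, from
#' (1, 1) down to (0, 0).
#'
#' @inheritParams auc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  pos <- to_positive(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  out <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !pos) / sum(!pos),
      tpr = sum(pred & pos) / sum(pos))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

accuracy_pct <- function(pred_labels, gold_labels) {
  100 * mean(as.character(pred_labels) == as.character(gold_labels))
}

#' Cross-validation scheme
#'
#' @param k Folds (study default 5).
#' @param repeats Repetitions of the whole k-fold split (study default 20).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Integer seed for the fold draws.
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(k = 5L, repeats = 20L, stratified = TRUE, seed = 1L) {
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Analysis pipeline specification
#'
#' Bundles the feature route and the classifier into one refittable unit so
#' that cross-validation and permutation testing can retrain everything —
#' vocabulary, normalisation, Gini feature selection, classifier — inside
#' each fold's training portion.
#'
#' @param classifier A [classifier_spec()], or the string
#'   `"w2v_inversion"` to use the embedding inversion classifier.
#' @param features `"bow"`, `"concepts"`, or `"none"` (rule- and
#'   inversion-based routes need no feature matrix).
#' @param k_features Gini-selection subset size (study default 100).
#' @param dictionary Concept dictionary for the `"concepts"` route.
#' @param embedding [embedding_config()] for the inversion route.
#' @param stopword_list Stop words for the BOW route.
#' @param min_doc_count BOW vocabulary pruning threshold.
#' @return A `pheno_pipeline` object.
#' @export
pheno_pipeline <- function(classifier = classifier_spec("random_forest"),
                           features = c("bow", "concepts", "none"),
                           k_features = 100L,
                           dictionary = default_concept_dictionary(),
                           embedding = embedding_config(),
                           stopword_list = stopwords_en(),
                           min_doc_count = 2L) {
  features <- match.arg(features)
  inversion <- identical(classifier, "w2v_inversion")
  if (!inversion) stopifnot(inherits(classifier, "classifier_spec"))
  if (inversion || (!inversion && classifier$family == "icd9_rule")) {
    features <- "none"
  }
  structure(list(classifier = classifier, features = features,
                 k_features = as.integer(k_features),
                 dictionary = dictionary, embedding = embedding,
                 stopword_list = stopword_list,
                 min_doc_count = as.integer(min_doc_count),
                 inversion = inversion),
            class = "pheno_pipeline")
}

#' @export
print.pheno_pipeline <- function(x, ...) {
  fam <- if (x$inversion) "w2v_inversion" else x$classifier$family
  cat(sprintf("<pheno_pipeline> %s on %s features (k = %d)\n",
              fam, x$features, x$k_features))
  invisible(x)
}

# Documents for a set of patients, on the route the pipeline needs.
pipeline_documents <- function(pipeline, patients) {
  if (x_route(pipeline) == "icd9") return(NULL)
  lapply(patients, aggregate_notes, stem = pipeline$inversion)
}

x_route <- function(pipeline) {
  if (pipeline$inversion) return("inversion")
  if (pipeline$classifier$family == "icd9_rule") return("icd9")
  pipeline$features
}

#' Fit a pipeline on training patients
#'
#' Trains the full route on the given patients (for a cohort with a split,
#' the TRAIN partition): feature construction and selection plus the
#' classifier, or the base-and-finetuned embedding models for the
#' inversion route. Nothing is fitted for the ICD-9 rule.
#'
#' @param pipeline A [pheno_pipeline()].
#' @param cohort A `pheno_cohort` (its TRAIN partition is used when a split
#'   is present), or a plain list of `patient_record`s.
#' @param labels Optional labels overriding the patients' gold labels
#'   (used internally by the permutation test).
#' @param seed Seed for the stochastic fitting steps (defaults to the
#'   classifier/embedding seed).
#' @return A `fitted_pipeline` object usable with `predict()`.
#' @export
fit_pipeline <- function(pipeline, cohort, labels = NULL, seed = NULL) {
  stopifnot(inherits(pipeline, "pheno_pipeline"))
  patients <- pipeline_patients(cohort, "TRAIN")
  if (is.null(labels)) {
    labels <- vapply(patients, `[[`, character(1), "gold_label")
  }
  if (is.null(seed)) {
    seed <- if (pipeline$inversion) pipeline$embedding$seed else pipeline$classifier$seed
  }
  fit_pipeline_impl(pipeline, patients,
                    documents = pipeline_documents(pipeline, patients),
                    labels = labels, seed = seed)
}

pipeline_patients <- function(cohort, partition) {
  if (inherits(cohort, "pheno_cohort")) {
    if (is.null(cohort$split)) return(cohort$patients)
    ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
    cohort$patients[cohort$split[ids] == partition]
  } else {
    cohort
  }
}

fit_pipeline_impl <- function(pipeline, patients, documents, labels, seed) {
  route <- x_route(pipeline)
  fitted <- switch(route,
    icd9 = list(),
    inversion = {
      cfg <- pipeline$embedding
      cfg$seed <- as.integer(seed)
      list(inv = w2v_inversion(documents, labels, config = cfg))
    },
    bow = {
      fm <- bow_matrix(documents, stopword_list = pipeline$stopword_list,
                       min_doc_count = pipeline$min_doc_count)
      vocab <- colnames(fm$values)
      fm <- normalize_features(fm)
      sel <- select_features(fm, labels, k = pipeline$k_features,
                             seed = seed)
      clf <- fit_classifier(pipeline$classifier, sel$matrix, labels)
      list(vocab = vocab, selected = colnames(sel$matrix$values),
           ranking = sel$ranking, classifier = clf)
    },
    concepts = {
      fm <- concept_matrix(documents, dictionary = pipeline$dictionary)
      fm <- suppressWarnings(normalize_features(fm))
      sel <- select_features(fm, labels, k = pipeline$k_features,
                             seed = seed)
      clf <- fit_classifier(pipeline$classifier, sel$matrix, labels)
      list(selected = colnames(sel$matrix$values), ranking = sel$ranking,
           classifier = clf)
    }
  )
  structure(c(list(pipeline = pipeline, route = route, seed = seed), fitted),
            class = "fitted_pipeline")
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf("<fitted_pipeline> route %s\n", x$route))
  invisible(x)
}

#' Predict with a fitted pipeline
#'
#' @param object A `fitted_pipeline`.
#' @param newdata A `pheno_cohort` (TEST partition when a split is
#'   present) or list of `patient_record`s.
#' @param partition Which partition of a cohort to score (default
#'   `"TEST"`).
#' @param ... Unused.
#' @return data.frame with `patient_id`, `label`, `score`.
#' @export
predict.fitted_pipeline <- function(object, newdata, partition = "TEST", ...) {
  patients <- pipeline_patients(newdata, partition)
  predict_pipeline_impl(object, patients,
                        pipeline_documents(object$pipeline, patients))
}

predict_pipeline_impl <- function(fitted, patients, documents) {
  switch(fitted$route,
    icd9 = {
      code <- fitted$pipeline$classifier$hyperparameters$code
      do.call(rbind, lapply(patients, icd9_classify, code = code))
    },
    inversion = {
      out <- predict(fitted$inv, documents)
      out[, c("patient_id", "label", "score")]
    },
    bow = {
      fm <- bow_matrix(documents, vocabulary = fitted$vocab,
                       stopword_list = fitted$pipeline$stopword_list)
      fm <- suppressWarnings(normalize_features(fm))
      fm$values <- fm$values[, fitted$selected, drop = FALSE]
      predict(fitted$classifier, fm)
    },
    concepts = {
      fm <- concept_matrix(documents,
                           dictionary = fitted$pipeline$dictionary)
      fm <- suppressWarnings(normalize_features(fm))
      fm$values <- fm$values[, fitted$selected, drop = FALSE]
      predict(fitted$classifier, fm)
    }
  )
}

# Precompute the raw per-document count matrix once for the resampling
# harnesses; per-fold refits then subset rows, which is identical to
# rebuilding from text (counts are deterministic per document) but avoids
# re-tokenising and re-stemming the corpus in every fold.
route_counts <- function(pipeline, documents) {
  switch(x_route(pipeline),
    bow = bow_matrix(documents, stopword_list = pipeline$stopword_list,
                     min_doc_count = 1L),
    concepts = concept_matrix(documents, dictionary = pipeline$dictionary),
    NULL)
}

# Fit the feature route + classifier on the training rows of a
# precomputed count matrix; vocabulary pruning, normalisation and Gini
# selection are all fitted on those rows only.
fit_fold <- function(pipeline, counts, rows_tr, labels_tr, seed) {
  sub <- counts$values[rows_tr, , drop = FALSE]
  if (pipeline$features == "bow") {
    keep <- Matrix::colSums(sub > 0) >= pipeline$min_doc_count
    if (!any(keep)) stop("empty vocabulary after pruning", call. = FALSE)
    sub <- sub[, keep, drop = FALSE]
  }
  fm <- suppressWarnings(
    normalize_features(feature_matrix(sub, type = counts$type)))
  sel <- select_features(fm, labels_tr, k = pipeline$k_features, seed = seed)
  clf <- fit_classifier(pipeline$classifier, sel$matrix, labels_tr)
  list(vocab = colnames(sub), selected = colnames(sel$matrix$values),
       classifier = clf)
}

predict_fold <- function(fold_fit, counts, rows_va) {
  sub <- counts$values[rows_va, fold_fit$vocab, drop = FALSE]
  fm <- suppressWarnings(
    normalize_features(feature_matrix(sub, type = counts$type)))
  fm$values <- fm$values[, fold_fit$selected, drop = FALSE]
  predict(fold_fit$classifier, fm)
}

# stratified fold assignment over patient source-ids: bootstrap duplicates
# always land in the same fold as their source to prevent leakage
assign_folds <- function(patients, labels, k, stratified) {
  src <- vapply(patients, function(p) {
    if (!is.null(p$source_id)) p$source_id else p$patient_id
  }, character(1))
  uniq <- unique(src)
  uniq_lab <- labels[match(uniq, src)]
  fold_of <- stats::setNames(integer(length(uniq)), uniq)
  if (stratified) {
    for (cls in unique(uniq_lab)) {
      ids <- sample(uniq[uniq_lab == cls])
      fold_of[ids] <- rep_len(sample(k), length(ids))
    }
  } else {
    fold_of[sample(uniq)] <- rep_len(sample(k), length(uniq))
  }
  unname(fold_of[src])
}

#' Repeated stratified cross-validation
#'
#' k-fold cross-validation repeated `repeats` times on the TRAIN partition.
#' Every fold refits the entire pipeline — vocabulary, normalisation, Gini
#' feature selection and classifier — on the fold's training portion only;
#' the TEST partition is never touched. Accuracy is reported on the 0-100
#' percent scale, AUC on 0-1; 95% confidence intervals for the means come
#' from the empirical distribution of the repeat-level means (normal
#' approximation), the CI method being stamped into the report.
#'
#' @param pipeline A [pheno_pipeline()].
#' @param cohort A `pheno_cohort` (TRAIN partition used when split).
#' @param scheme A [cv_scheme()].
#' @return An `eval_report` with `folds` (per-fold data.frame),
#'   `cv_accuracy`, `cv_auc`, `ci_accuracy`, `ci_auc`, `ci_method`.
#' @export
run_cv <- function(pipeline, cohort, scheme = cv_scheme()) {
  stopifnot(inherits(scheme, "cv_scheme"))
  patients <- pipeline_patients(cohort, "TRAIN")
  labels <- vapply(patients, `[[`, character(1), "gold_label")
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  documents <- pipeline_documents(pipeline, patients)
  counts <- route_counts(pipeline, documents)
  folds_out <- with_seed(scheme$seed, {
    res <- list()
    for (rep_i in seq_len(scheme$repeats)) {
      fold <- assign_folds(patients, labels, scheme$k, scheme$stratified)
      for (f in seq_len(scheme$k)) {
        tr <- which(fold != f)
        va <- which(fold == f)
        if (length(intersect(ids[tr], ids[va]))) {
          stop("leakage: validation ids intersect training ids",
               call. = FALSE)
        }
        if (length(unique(labels[va])) < 2L) next
        fold_seed <- derive_seed(scheme$seed, rep_i * scheme$k + f)
        if (!is.null(counts)) {
          fitted <- fit_fold(pipeline, counts, tr, labels[tr], fold_seed)
          pred <- predict_fold(fitted, counts, va)
        } else {
          fitted <- fit_pipeline_impl(
            pipeline, patients[tr],
            documents = if (is.null(documents)) NULL else documents[tr],
            labels = labels[tr], seed = fold_seed)
          pred <- predict_pipeline_impl(
            fitted, patients[va],
            if (is.null(documents)) NULL else documents[va])
        }
        res[[length(res) + 1L]] <- data.frame(
          repeat_i = rep_i, fold = f,
          accuracy = accuracy_pct(pred$label, labels[va]),
          auc = auc(pred$score, labels[va]))
      }
    }
    do.call(rbind, res)
  })
  rep_means <- stats::aggregate(cbind(accuracy, auc) ~ repeat_i,
                                data = folds_out, FUN = mean)
  ci <- function(v) {
    m <- mean(v)
    half <- if (length(v) > 1L) 1.96 * stats::sd(v) / sqrt(length(v)) else 0
    c(lower = m - half, upper = m + half)
  }
  structure(
    list(folds = folds_out,
         cv_accuracy = mean(folds_out$accuracy),
         cv_auc = mean(folds_out$auc),
         ci_accuracy = ci(rep_means$accuracy),
         ci_auc = ci(rep_means$auc),
         ci_method = "normal approximation over repeat-level means",
         scheme = scheme),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %dx%d-fold CV\n", x$scheme$repeats, x$scheme$k))
  cat(sprintf("  CV accuracy: %.3f%% [%.3f, %.3f]\n", x$cv_accuracy,
              x$ci_accuracy[["lower"]], x$ci_accuracy[["upper"]]))
  cat(sprintf("  CV AUC: %.3f [%.3f, %.3f]  (CI: %s)\n", x$cv_auc,
              x$ci_auc[["lower"]], x$ci_auc[["upper"]], x$ci_method))
  if (!is.null(x$test_accuracy)) {
    cat(sprintf("  Test accuracy: %.3f%%, AUC %.3f\n", x$test_accuracy,
                x$test_auc))
  }
  invisible(x)
}

#' Evaluate a fitted pipeline on the external test partition
#'
#' @param fitted A `fitted_pipeline` (trained on TRAIN only).
#' @param cohort A `pheno_cohort` with a TEST partition.
#' @return List with `accuracy` (percent), `auc`, `roc` (ROC points),
#'   `predictions`.
#' @export
evaluate_test <- function(fitted, cohort) {
  if (!inherits(fitted, "fitted_pipeline")) {
    stop("`fitted` must be a fitted pipeline", call. = FALSE)
  }
  patients <- pipeline_patients(cohort, "TEST")
  if (!length(patients)) stop("cohort has no TEST partition", call. = FALSE)
  gold <- vapply(patients, `[[`, character(1), "gold_label")
  pred <- predict(fitted, cohort, partition = "TEST")
  list(accuracy = accuracy_pct(pred$label, gold),
       auc = auc(pred$score, gold),
       roc = roc_points(pred$score, gold),
       predictions = cbind(pred, gold_label = gold))
}

#' Label-permutation null distribution of the AUC
#'
#' For each permutation the class labels of the evaluation patients are
#' randomly scrambled, the full pipeline is refit on the permuted labels,
#' and the AUC of the refit pipeline is computed against those same
#' permuted labels on held-out folds (k-fold cross-validation, pooled
#' out-of-fold scores). The resulting distribution is centred on 0.5 —
#' a classifier given label-independent targets cannot beat chance —
#' and quantifies how far a real result is from random. Reports the mean
#' with normal-approximation confidence intervals for the mean at 95% and
#' 99%, plus the sample quantiles.
#'
#' @param pipeline A [pheno_pipeline()].
#' @param cohort A `pheno_cohort` (TRAIN partition used when split).
#' @param n_permutations Number of label permutations (>= 100; default
#'   200).
#' @param k Folds used to hold out evaluation patients within each
#'   permutation.
#' @param seed Integer seed.
#' @return A `permutation_null` object: `n_permutations`, `auc_samples`,
#'   `mean_auc`, `ci_95`, `ci_99`, `quantiles`.
#' @export
permutation_test <- function(pipeline, cohort, n_permutations = 200L,
                             k = 5L, seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L) {
    stop("`n_permutations` must be at least 100", call. = FALSE)
  }
  patients <- pipeline_patients(cohort, "TRAIN")
  labels <- vapply(patients, `[[`, character(1), "gold_label")
  documents <- pipeline_documents(pipeline, patients)
  counts <- route_counts(pipeline, documents)
  aucs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(pi) {
      perm <- sample(labels)
      fold <- assign_folds(patients, perm, k, stratified = TRUE)
      fold_aucs <- numeric(0)
      for (f in seq_len(k)) {
        tr <- which(fold != f)
        va <- which(fold == f)
        fold_seed <- derive_seed(seed, pi * k + f)
        if (!is.null(counts)) {
          fitted <- fit_fold(pipeline, counts, tr, perm[tr], fold_seed)
          pred <- predict_fold(fitted, counts, va)
        } else {
          fitted <- fit_pipeline_impl(
            pipeline, patients[tr],
            documents = if (is.null(documents)) NULL else documents[tr],
            labels = perm[tr], seed = fold_seed)
          pred <- predict_pipeline_impl(
            fitted, patients[va],
            if (is.null(documents)) NULL else documents[va])
        }
        # fold-level AUC: an exact rank statistic on the held-out fold,
        # centred at 1/2 under label permutation; fold AUCs are averaged
        # rather than pooling scores across differently-fitted fold models
        fold_aucs <- c(fold_aucs, auc(pred$score, perm[va]))
      }
      mean(fold_aucs)
    }, numeric(1))
  })
  m <- mean(aucs)
  se <- stats::sd(aucs) / sqrt(length(aucs))
  structure(
    list(n_permutations = n_permutations, auc_samples = aucs,
         mean_auc = m,
         ci_95 = c(lower = m - 1.96 * se, upper = m + 1.96 * se),
         ci_99 = c(lower = m - 2.576 * se, upper = m + 2.576 * se),
         quantiles = stats::quantile(aucs, c(0.025, 0.25, 0.5, 0.75, 0.975))),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d permutations: mean AUC %.3f, 95%% CI (%.3f, %.3f), 99%% CI (%.3f, %.3f)\n",
    x$n_permutations, x$mean_auc, x$ci_95[["lower"]], x$ci_95[["upper"]],
    x$ci_99[["lower"]], x$ci_99[["upper"]]))
  invisible(x)
}

#' Prepare a cohort for analysis
#'
#' The fixed order of corpus preparation: keyword filtering, external
#' holdout split, then bootstrap class balancing within each partition.
#'
#' @param cohort A `pheno_cohort` from [generate_cohort()].
#' @param keyword_stem Note filter stem (default `"rheumatol"`).
#' @param n_test External holdout size (default from the config).
#' @param seed Seed for the split and balancing draws.
#' @return The prepared cohort.
#' @export
prepare_cohort <- function(cohort, keyword_stem = "rheumatol",
                           n_test = cohort$config$holdout,
                           seed = cohort$config$seed) {
  cohort <- filter_cohort(cohort, keyword_stem)
  cohort <- holdout_split(cohort, n_test = n_test, seed = derive_seed(seed, 101))
  balance_by_bootstrap(cohort, seed = derive_seed(seed, 202))
}
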
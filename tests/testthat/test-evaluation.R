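# AUC, ROC export, the repeated-CV harness, external-test scoring and the
# pipeline plumbing.

test_that("rank AUC reproduces the worked example and edge cases", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c("SLE", "SLE", "CONTROL",
                                            "CONTROL")), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # with ties
    l <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(s, l), auc(plogis(3 * s - 1), l))
    expect_equal(auc(s, l), auc(rank(s), l))
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    s <- round(runif(n), 2)
    l <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    ref <- suppressMessages(as.numeric(pROC::auc(l, s, direction = "<")))
    expect_equal(auc(s, l), ref)
  }
})

test_that("trapezoidal area under the ROC points equals the rank AUC", {
  set.seed(7)
  s <- round(runif(40), 2)
  l <- rep(c(1, 0), 20)
  roc <- roc_points(s, l)
  expect_equal(roc$fpr[1], 1)
  expect_equal(roc$tpr[1], 1)
  expect_equal(roc$fpr[nrow(roc)], 0)
  expect_equal(roc$tpr[nrow(roc)], 0)
  # integrate in decreasing-threshold order so fpr and tpr ascend together
  o <- order(roc$threshold, decreasing = TRUE)
  trapz <- sum(diff(roc$fpr[o]) *
                 (utils::head(roc$tpr[o], -1) + utils::tail(roc$tpr[o], -1)) / 2)
  expect_equal(trapz, auc(s, l))
})

test_that("an oracle pipeline scores perfectly in repeated CV", {
  # noiseless ICD-9 codes make the rule classifier a gold-label oracle
  coh <- generate_cohort(synth_config(n_patients = 60, holdout = 20,
                                      icd9_sensitivity = 1,
                                      icd9_specificity = 1, seed = 19))
  coh <- prepare_cohort(coh)
  pl <- pheno_pipeline(classifier_spec("icd9_rule"))
  rep <- run_cv(pl, coh, cv_scheme(k = 5, repeats = 2, seed = 3))
  expect_identical(nrow(rep$folds), 10L)
  expect_equal(rep$cv_accuracy, 100)
  expect_equal(rep$cv_auc, 1)
  expect_equal(unname(diff(rep$ci_accuracy)), 0)
  te <- evaluate_test(fit_pipeline(pl, coh), coh)
  expect_equal(te$accuracy, 100)
  expect_equal(te$auc, 1)
  expect_named(te$predictions,
               c("patient_id", "label", "score", "gold_label"))
})

test_that("CV folds partition the training ids with balanced strata", {
  coh <- prepare_cohort(small_cohort(n = 80, seed = 23, holdout = 20))
  patients <- lupusnlp:::pipeline_patients(coh, "TRAIN")
  labels <- vapply(patients, `[[`, character(1), "gold_label")
  set.seed(1)
  fold <- lupusnlp:::assign_folds(patients, labels, k = 5,
                                  stratified = TRUE)
  expect_setequal(unique(fold), 1:5)
  expect_identical(length(fold), length(patients))
  # on a balanced partition, stratified folds keep the classes within the
  # round-robin remainder of one per class
  for (f in 1:5) {
    tab <- table(factor(labels[fold == f], levels = pheno_levels()))
    expect_lte(abs(tab[["SLE"]] - tab[["CONTROL"]]), 2)
  }
})

test_that("a learning pipeline beats chance in CV on class-correlated text", {
  coh <- prepare_cohort(small_cohort(n = 120, seed = 29, holdout = 20))
  pl <- pheno_pipeline(classifier_spec("random_forest", trees = 150,
                                       seed = 2),
                       features = "bow", k_features = 50)
  rep <- run_cv(pl, coh, cv_scheme(k = 5, repeats = 2, seed = 4))
  expect_gt(rep$cv_auc, 0.8)
  expect_true(rep$ci_auc[["lower"]] <= rep$cv_auc &&
                rep$cv_auc <= rep$ci_auc[["upper"]])
  expect_match(rep$ci_method, "repeat-level")
})

test_that("concept-route pipeline runs end to end", {
  coh <- prepare_cohort(small_cohort(n = 80, seed = 31, holdout = 20))
  pl <- pheno_pipeline(classifier_spec("random_forest", trees = 100,
                                       seed = 5), features = "concepts",
                       k_features = 15)
  f <- fit_pipeline(pl, coh)
  te <- suppressWarnings(evaluate_test(f, coh))
  expect_gt(te$auc, 0.7)
})

test_that("permutation test guards its sample-size precondition", {
  coh <- prepare_cohort(small_cohort(n = 40, seed = 37, holdout = 0))
  pl <- pheno_pipeline(classifier_spec("random_forest"))
  expect_error(permutation_test(pl, coh, n_permutations = 50), "at least 100")
})

test_that("splits file records partitions and bootstrap provenance", {
  coh <- prepare_cohort(small_cohort(n = 40, seed = 41, holdout = 10))
  dir <- withr::local_tempdir()
  write_splits(coh, dir)
  df <- read.csv(file.path(dir, "splits.csv"))
  expect_setequal(unique(df$partition), c("TRAIN", "TEST"))
  expect_true(is.logical(df$is_bootstrap_duplicate))
})
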
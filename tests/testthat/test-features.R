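# Bag-of-words counting, negation-aware concept matching, normalisation
# and Gini feature selection.

test_that("bag-of-words counts stems per document", {
  docs <- list(make_document("lupus lupus rash", "A"),
               make_document("lupus lupus rash", "B"),
               make_document("patient does not have lupus", "C"))
  fm <- bow_matrix(docs, min_doc_count = 1)
  m <- as.matrix(fm$values)
  expect_identical(m["A", "lupus"], 2)
  expect_identical(m["A", "rash"], 1)
  expect_identical(m["A", ], m["B", ])
  # the negator survives the stop list and is counted alongside "lupus"
  expect_identical(m["C", "not"], 1)
  expect_identical(m["C", "lupus"], 1)
  # row sums equal retained token counts
  lens <- vapply(docs, function(d) length(preprocess_tokens(d$text)),
                 numeric(1))
  expect_equal(unname(Matrix::rowSums(fm$values)), lens)
})

test_that("vocabulary is fixed by the training documents", {
  train <- list(make_document("alpha beta alpha", "T1"),
                make_document("alpha beta gamma", "T2"))
  fm <- bow_matrix(train, min_doc_count = 2)
  expect_setequal(colnames(fm$values), c("alpha", "beta"))
  test <- list(make_document("alpha delta unseen", "X"))
  fm_test <- bow_matrix(test, vocabulary = colnames(fm$values))
  expect_identical(colnames(fm_test$values), colnames(fm$values))
  expect_identical(as.numeric(fm_test$values["X", ]), c(1, 0))
  expect_error(bow_matrix(list(make_document("solo", "Y")),
                          min_doc_count = 2), "empty vocabulary")
})

test_that("negated mentions decrement their concept", {
  docs <- list(make_document("does not have lupus", "A"),
               make_document("patient has lupus", "B"),
               make_document("no relevant findings here", "C"))
  cm <- as.matrix(concept_matrix(docs)$values)
  expect_identical(cm["A", "C0024141"], -1L)
  expect_identical(cm["B", "C0024141"], 1L)
  expect_true(all(cm["C", ] == 0L))
})

test_that("longest match wins and consumes its span", {
  docs <- list(make_document("history of lupus nephritis", "A"))
  cm <- as.matrix(concept_matrix(docs)$values)
  expect_identical(cm["A", "C0024143"], 1L)  # lupus nephritis
  expect_identical(cm["A", "C0024141"], 0L)  # plain lupus not also counted
})

test_that("ambiguous abbreviations increment every mapped concept", {
  docs <- list(make_document("assessment SLE today", "A"))
  cm <- as.matrix(concept_matrix(docs)$values)
  expect_identical(cm["A", "C0024141"], 1L)  # systemic lupus erythematosus
  expect_identical(cm["A", "C0014060"], 1L)  # St. Louis Encephalitis
  # removing the ambiguous mapping strictly decreases the encephalitis sum
  dict <- unclass(default_concept_dictionary())
  dict$C0014060 <- setdiff(dict$C0014060, "sle")
  cm2 <- as.matrix(concept_matrix(docs,
                                  dictionary = concept_dictionary(dict))$values)
  expect_lt(sum(cm2[, "C0014060"]), sum(cm[, "C0014060"]))
})

test_that("negation window is same-sentence and bounded", {
  far <- make_document("no history of any prior documented lupus", "A")
  cm <- as.matrix(concept_matrix(list(far), window = 5)$values)
  expect_identical(cm["A", "C0024141"], 1L)  # cue 6 tokens away: affirmed
  cross <- make_document("findings negative. lupus confirmed", "B")
  cm2 <- as.matrix(concept_matrix(list(cross))$values)
  expect_identical(cm2["B", "C0024141"], 1L)  # cue in previous sentence
})

test_that("L1 normalisation scales rows and guards its state", {
  m <- matrix(c(2, 1, 1, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("x", "y", "z")))
  fm <- feature_matrix(m, type = "bow")
  expect_warning(norm <- normalize_features(fm), "all-zero")
  expect_equal(as.numeric(norm$values["A", ]), c(0.5, 0.25, 0.25))
  expect_equal(as.numeric(norm$values["B", ]), c(0, 0, 0))
  expect_error(normalize_features(norm), "already normalized")
})

test_that("Gini selection finds planted features and keeps its contracts", {
  set.seed(31)
  n <- 200
  y <- rep(c("SLE", "CONTROL"), length.out = n)
  x <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(sprintf("P%03d", 1:n),
                              sprintf("v%03d", 1:100)))
  x[, 1] <- as.numeric(y == "SLE") + rnorm(n, sd = 0.01)
  x[, 2] <- -as.numeric(y == "SLE") + rnorm(n, sd = 0.01)
  fm <- feature_matrix(x, type = "concept")
  out <- select_features(fm, y, k = 10, seed = 5)
  expect_setequal(out$ranking$feature[1:2], c("v001", "v002"))
  expect_identical(ncol(out$matrix$values), 10L)
  expect_true(all(out$ranking$vimp >= 0))
  expect_equal(sum(out$ranking$vimp), 1)
  # top-k of the ranking equals the retained columns
  expect_setequal(colnames(out$matrix$values), out$ranking$feature[1:10])
  # k at or above the width is the identity (warning only when above)
  same <- select_features(fm, y, k = 100, seed = 5)
  expect_identical(colnames(same$matrix$values), colnames(x))
  expect_warning(select_features(fm, y, k = 101, seed = 5), "retaining all")
})

test_that("feature matrices round-trip through MatrixMarket files", {
  docs <- list(make_document("lupus rash lupus", "A"),
               make_document("rash fatigue", "B"))
  fm <- bow_matrix(docs, min_doc_count = 1)
  dir <- withr::local_tempdir()
  write_feature_matrix(fm, dir, prefix = "bow")
  m <- Matrix::readMM(file.path(dir, "bow.mtx"))
  expect_equal(as.matrix(m),
               unname(as.matrix(fm$values)))
  expect_identical(readLines(file.path(dir, "bow_features.txt")),
                   colnames(fm$values))
  expect_identical(readLines(file.path(dir, "bow_rows.txt")), c("A", "B"))
})
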
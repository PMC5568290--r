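# Skip-gram / hierarchical-softmax embedding training, exact sentence
# likelihoods, per-class fine-tuning and the inversion classifier.

toy_config <- function(min_count = 1) {
  embedding_config(dimension = 8, window = 2, min_count = min_count,
                   epochs_base = 3, epochs_finetune = 3, seed = 5)
}

toy_sentences <- function(n = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sample(c("alpha", "beta", "gamma", "delta"), 5, replace = TRUE)
  })
}

test_that("vocabulary threshold and metadata behave as configured", {
  sents <- toy_sentences()
  expect_error(train_base(sents, toy_config(min_count = 10000)),
               "vocabulary is empty")
  m <- train_base(sents, toy_config())
  expect_identical(m$config$dimension, 8L)
  expect_identical(m$config$window, 2L)
  expect_identical(nrow(m$vocab), 4L)
  expect_identical(ncol(m$syn0), 8L)
  expect_identical(nrow(m$syn1), 3L)
})

test_that("Huffman codes satisfy the Kraft equality", {
  sents <- toy_sentences(seed = 3)
  m <- train_base(sents, toy_config())
  lens <- lengths(m$code)
  expect_identical(lengths(m$point), lens)
  expect_equal(sum(2^-lens), 1)
  expect_true(all(unlist(m$code) %in% c(0L, 1L)))
})

test_that("training is deterministic under a fixed seed", {
  sents <- toy_sentences(seed = 2)
  m1 <- train_base(sents, toy_config())
  m2 <- train_base(sents, toy_config())
  expect_identical(m1$syn0, m2$syn0)
  expect_identical(m1$syn1, m2$syn1)
})

test_that("sentence log-likelihood is exact against a scalar oracle", {
  m <- train_base(toy_sentences(seed = 4), toy_config())
  sent <- c("alpha", "beta", "gamma")
  got <- sentence_loglik(m, sent)
  ids <- match(sent, m$vocab$word)
  ll <- 0
  np <- 0
  for (t in seq_along(ids)) {
    for (j in c(-2, -1, 1, 2)) {
      ct <- t + j
      if (ct >= 1 && ct <= length(ids)) {
        cd <- m$code[[ids[ct]]]
        pt <- m$point[[ids[ct]]]
        for (k in seq_along(cd)) {
          x <- sum(m$syn0[ids[t], ] * m$syn1[pt[k], ])
          ll <- ll + plogis((1 - 2 * cd[k]) * x, log.p = TRUE)
        }
        np <- np + 1
      }
    }
  }
  expect_lt(abs(got$ll - ll), 1e-9)
  expect_identical(got$n_pairs, as.integer(np))
  expect_lte(got$ll, 0)
})

test_that("unscoreable sentences return the exclusion sentinel", {
  m <- train_base(toy_sentences(), toy_config())
  expect_true(is.na(sentence_loglik(m, c("zzz", "qqq", "www"))$ll))
  expect_true(is.na(sentence_loglik(m, "alpha")$ll))
  expect_identical(sentence_loglik(m, c("zzz"))$n_pairs, 0L)
})

test_that("fine-tuning copies are independent of the base and one another", {
  sents <- toy_sentences(seed = 6)
  base <- train_base(sents, toy_config())
  snapshot <- base$syn0
  probe <- c("alpha", "beta", "gamma")
  none <- finetune_embedding(base, sents[1:10], epochs = 0)
  expect_identical(sentence_loglik(none, probe)$ll,
                   sentence_loglik(base, probe)$ll)
  tuned_a <- finetune_embedding(base, sents[1:20], epochs = 3)
  tuned_b <- finetune_embedding(base, sents[21:40], epochs = 3)
  expect_identical(base$syn0, snapshot)  # base untouched
  b_before <- sentence_loglik(tuned_b, probe)$ll
  tuned_a2 <- finetune_embedding(base, sents[1:20], epochs = 5)
  expect_identical(sentence_loglik(tuned_b, probe)$ll, b_before)
  expect_error(finetune_embedding(base, list()), "empty")
})

test_that("each class model prefers held-out sentences of its own class", {
  corp <- simulate_inversion_corpus(n_patients = 60,
                                    sentences_per_patient = 20,
                                    signal_rate = 0.5, seed = 9)
  cfg <- embedding_config(dimension = 16, window = 5, min_count = 3,
                          epochs_base = 3, epochs_finetune = 5, seed = 2)
  tr <- 1:40
  te <- 41:60
  inv <- w2v_inversion(corp$documents[tr], corp$labels[tr], config = cfg)
  mean_ll <- function(model, docs) {
    lls <- unlist(lapply(docs, function(d) {
      vapply(d$sentences, function(s) {
        sc <- sentence_loglik(model, s)
        if (is.na(sc$ll)) NA_real_ else sc$ll / sc$n_pairs
      }, numeric(1))
    }))
    mean(lls, na.rm = TRUE)
  }
  sle_docs <- corp$documents[te][corp$labels[te] == "SLE"]
  ctl_docs <- corp$documents[te][corp$labels[te] == "CONTROL"]
  expect_gt(mean_ll(inv$class_models$SLE, sle_docs),
            mean_ll(inv$class_models$CONTROL, sle_docs))
  expect_gt(mean_ll(inv$class_models$CONTROL, ctl_docs),
            mean_ll(inv$class_models$SLE, ctl_docs))
})

test_that("inversion posterior is a safe softmax", {
  expect_equal(unname(inversion_posterior(c(SLE = -5, CONTROL = -5))),
               c(0.5, 0.5))
  p <- inversion_posterior(c(SLE = -10, CONTROL = -12))
  expect_equal(unname(p), c(0.8808, 0.1192), tolerance = 1e-3)
  set.seed(1)
  r <- inversion_posterior(c(A = rnorm(1), B = rnorm(1), C = rnorm(1)))
  expect_equal(sum(r), 1)
  # overflow safety
  big <- inversion_posterior(c(SLE = -1e6, CONTROL = -1e6 - 2))
  expect_true(all(is.finite(big)))
})

test_that("patients are labelled by majority vote with score = SLE fraction", {
  corp <- simulate_inversion_corpus(n_patients = 40,
                                    sentences_per_patient = 9,
                                    signal_rate = 0.8, seed = 3)
  cfg <- embedding_config(dimension = 16, window = 5, min_count = 3,
                          epochs_base = 3, epochs_finetune = 5, seed = 8)
  inv <- w2v_inversion(corp$documents, corp$labels, config = cfg)
  doc <- corp$documents[[1]]
  sc <- lupusnlp:::score_sentences(inv, doc)
  votes <- inv$classes[max.col(sc$scores, ties.method = "first")]
  out <- classify_patient(inv, doc)
  expect_equal(out$score, mean(votes == "SLE"))
  maj <- names(which.max(table(factor(votes, levels = inv$classes))))
  if (length(unique(table(votes))) > 1) {
    expect_identical(out$label, maj)
  }
  # a document with no in-vocabulary sentences abstains at 0.5
  empty_doc <- make_document("zzz qqq. www rrr.", "E")
  ab <- classify_patient(inv, empty_doc)
  expect_identical(ab$label, "ABSTAIN")
  expect_identical(ab$score, 0.5)
})
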
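# Classification by Bayesian inversion of distributed language models:
# a base skip-gram embedding trained on all training sentences, one
# fine-tuned copy per class, exact per-sentence log-likelihoods through the
# hierarchical-softmax tree, and patient labels by majority vote over
# sentence-level decisions.

#' Embedding model configuration
#'
#' Hyperparameters of the skip-gram/hierarchical-softmax embedding. The
#' defaults are the study settings: 500 dimensions, context window 5, and a
#' minimum vocabulary count of 20 (the "minimum word count" is read as the
#' vocabulary frequency threshold; an optional literal sentence-length
#' filter is available as `min_sentence_length`, default off — see the
#' methods vignette for the ambiguity).
#'
#' @param dimension Embedding dimension d.
#' @param window Context window c (tokens on each side).
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary.
#' @param epochs_base,epochs_finetune Training passes for the base model and
#'   for each per-class fine-tune.
#' @param alpha,alpha_min Initial and floor learning rate (linear decay).
#' @param dynamic_window If `TRUE` (default) the effective window for each
#'   center word is drawn uniformly from 1..`window` during training, the
#'   classic skip-gram scheme that upweights near contexts. Scoring always
#'   uses the full window.
#' @param min_sentence_length Optional sentence-length filter applied to
#'   training sentences (0 = off).
#' @param seed Integer seed; fully determines training (single-threaded).
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(dimension = 500L, window = 5L, min_count = 20L,
                             epochs_base = 5L, epochs_finetune = 5L,
                             alpha = 0.025, alpha_min = 1e-4,
                             dynamic_window = TRUE,
                             min_sentence_length = 0L, seed = 1L) {
  stopifnot(dimension >= 1L, window >= 1L, min_count >= 1L,
            epochs_base >= 1L, epochs_finetune >= 0L, alpha > 0)
  structure(
    list(dimension = as.integer(dimension), window = as.integer(window),
         min_count = as.integer(min_count),
         epochs_base = as.integer(epochs_base),
         epochs_finetune = as.integer(epochs_finetune),
         alpha = alpha, alpha_min = alpha_min,
         dynamic_window = isTRUE(dynamic_window),
         min_sentence_length = as.integer(min_sentence_length),
         seed = as.integer(seed)),
    class = "embedding_config"
  )
}

# Huffman coding of the vocabulary (words ordered by descending count).
# Inner nodes are numbered 1..V-1 (1-based rows of syn1; converted to
# 0-based at the C++ boundary); for each word the root-to-leaf path is a
# vector of inner-node rows plus a 0/1 branch code.
build_huffman <- function(counts) {
  V <- length(counts)
  if (V < 2L) stop("vocabulary must contain at least 2 words", call. = FALSE)
  cnt <- c(as.numeric(counts), rep(Inf, V - 1L))
  binary <- integer(2L * V - 1L)
  parent <- integer(2L * V - 1L)
  pos1 <- V
  pos2 <- V + 1L
  for (a in seq_len(V - 1L)) {
    if (pos1 >= 1L && cnt[pos1] < cnt[pos2]) {
      min1 <- pos1; pos1 <- pos1 - 1L
    } else {
      min1 <- pos2; pos2 <- pos2 + 1L
    }
    if (pos1 >= 1L && cnt[pos1] < cnt[pos2]) {
      min2 <- pos1; pos1 <- pos1 - 1L
    } else {
      min2 <- pos2; pos2 <- pos2 + 1L
    }
    cnt[V + a] <- cnt[min1] + cnt[min2]
    parent[min1] <- V + a
    parent[min2] <- V + a
    binary[min2] <- 1L
  }
  root <- 2L * V - 1L
  code <- vector("list", V)
  point <- vector("list", V)
  for (a in seq_len(V)) {
    b <- a
    cd <- integer(0)
    pt <- integer(0)
    while (b != root) {
      cd <- c(binary[b], cd)
      pt <- c(parent[b] - V, pt)
      b <- parent[b]
    }
    code[[a]] <- cd
    point[[a]] <- pt
  }
  list(code = code, point = point)
}

# Vocabulary: words with frequency >= min_count, ordered by count
# descending then word ascending (deterministic).
build_vocab <- function(sentences, min_count) {
  tab <- table(unlist(sentences, use.names = FALSE))
  tab <- tab[tab >= min_count]
  if (!length(tab)) {
    stop("no word reaches min_count = ", min_count,
         "; vocabulary is empty", call. = FALSE)
  }
  df <- data.frame(word = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$word), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

points0 <- function(point) lapply(point, function(p) as.integer(p - 1L))

# sentences as 0-based in-vocabulary id vectors; OOV tokens dropped
sentences_to_ids <- function(sentences, vocab_words, keep_oov = FALSE) {
  lapply(sentences, function(s) {
    idx <- match(s, vocab_words)
    if (keep_oov) {
      idx[is.na(idx)] <- 0L
      as.integer(idx - 1L)   # OOV becomes -1
    } else {
      as.integer(idx[!is.na(idx)] - 1L)
    }
  })
}

apply_sentence_filter <- function(sentences, config) {
  if (config$min_sentence_length > 0L) {
    sentences <- sentences[lengths(sentences) >= config$min_sentence_length]
  }
  sentences
}

#' Train the base skip-gram embedding model
#'
#' Trains a skip-gram model with hierarchical-softmax output (mandatory
#' here: the inversion classifier needs exact sentence likelihoods) on all
#' training sentences. Words below `min_count` are excluded from the
#' vocabulary; training is single-threaded with an internal seeded RNG, so
#' a fixed config yields a byte-identical model.
#'
#' @param sentences List of character token vectors (stemmed).
#' @param config An [embedding_config()].
#' @return An `embedding_model`: vocabulary with counts, input vectors
#'   (`syn0`, |V| x d), Huffman inner-node vectors (`syn1`), per-word path
#'   codes, and the config.
#' @export
train_base <- function(sentences, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  sentences <- apply_sentence_filter(sentences, config)
  if (!length(sentences)) stop("no training sentences", call. = FALSE)
  vocab <- build_vocab(sentences, config$min_count)
  V <- nrow(vocab)
  d <- config$dimension
  tree <- build_huffman(vocab$count)
  syn0 <- with_seed(config$seed,
                    matrix(stats::runif(V * d, -0.5, 0.5) / d, nrow = V))
  syn1 <- matrix(0, nrow = V - 1L, ncol = d)
  ids <- sentences_to_ids(sentences, vocab$word)
  ids <- ids[lengths(ids) > 0L]
  out <- cpp_train_sg_hs(ids, syn0, syn1, tree$code, points0(tree$point),
                         config$epochs_base, config$window, config$alpha,
                         config$alpha_min, config$seed,
                         config$dynamic_window)
  structure(
    list(vocab = vocab, syn0 = out$syn0, syn1 = out$syn1,
         code = tree$code, point = tree$point,
         point0 = points0(tree$point), config = config,
         trained_words = out$trained_words),
    class = "embedding_model"
  )
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> |V| = %d, d = %d, window = %d, min_count = %d\n",
              nrow(x$vocab), x$config$dimension, x$config$window,
              x$config$min_count))
  invisible(x)
}

#' Fine-tune a copy of the base model on one class corpus
#'
#' Continues training of a deep copy of `base` on the sentences of a single
#' class; the base model is left untouched and the vocabulary (and Huffman
#' tree) are frozen to the base's, so all class models score over the same
#' support. With `epochs = 0` the returned model is an exact copy of the
#' base.
#'
#' @param base A trained `embedding_model`.
#' @param class_sentences List of character token vectors for one class.
#' @param epochs Fine-tuning passes (default from the base config).
#' @param seed Seed for the fine-tuning pass (default derived from base).
#' @return A fine-tuned `embedding_model`.
#' @export
finetune_embedding <- function(base, class_sentences,
                               epochs = base$config$epochs_finetune,
                               seed = base$config$seed + 1L) {
  stopifnot(inherits(base, "embedding_model"))
  class_sentences <- apply_sentence_filter(class_sentences, base$config)
  if (!length(class_sentences)) {
    stop("class corpus is empty", call. = FALSE)
  }
  model <- base
  if (epochs == 0L) return(model)
  ids <- sentences_to_ids(class_sentences, base$vocab$word)
  ids <- ids[lengths(ids) > 0L]
  if (!length(ids)) stop("class corpus has no in-vocabulary tokens", call. = FALSE)
  out <- cpp_train_sg_hs(ids, base$syn0, base$syn1, base$code,
                         points0(base$point),
                         as.integer(epochs), base$config$window,
                         base$config$alpha, base$config$alpha_min,
                         as.integer(seed), base$config$dynamic_window)
  model$syn0 <- out$syn0
  model$syn1 <- out$syn1
  model$trained_words <- base$trained_words + out$trained_words
  model
}

#' Exact sentence log-likelihood under an embedding model
#'
#' Scores a tokenised sentence as the sum over all ordered skip-gram pairs
#' (offsets 1..window on either side) of `log P(context | center)`, each
#' conditional computed exactly as the product of sigmoids along the
#' context word's hierarchical-softmax path. Out-of-vocabulary tokens are
#' skipped. A sentence with fewer than two in-vocabulary tokens has no
#' skip-gram pairs; its log-likelihood is undefined and `NA` is returned
#' (such sentences are excluded from patient voting).
#'
#' @param model An `embedding_model`.
#' @param sentence Character vector of tokens.
#' @return List with `ll` (log-likelihood, `NA` if unscoreable) and
#'   `n_pairs` (number of scored skip-gram pairs).
#' @export
sentence_loglik <- function(model, sentence) {
  stopifnot(inherits(model, "embedding_model"))
  ids <- match(sentence, model$vocab$word)
  ids <- as.integer(ids[!is.na(ids)] - 1L)
  if (length(ids) < 2L) return(list(ll = NA_real_, n_pairs = 0L))
  pt0 <- if (is.null(model$point0)) points0(model$point) else model$point0
  out <- cpp_sentence_loglik(ids, model$syn0, model$syn1, model$code,
                             pt0, model$config$window)
  list(ll = out[[1L]], n_pairs = as.integer(out[[2L]]))
}

#' Posterior class probabilities from per-class log-likelihoods
#'
#' Softmax of `ll + log(prior)` with max-subtraction for overflow safety.
#'
#' @param ll Named numeric vector of per-class log-likelihoods.
#' @param priors Named numeric vector of prior class probabilities
#'   (defaults to uniform); must sum to 1.
#' @return Named numeric vector of posterior probabilities summing to 1.
#' @examples
#' inversion_posterior(c(SLE = -10, CONTROL = -12))
#' @export
inversion_posterior <- function(ll, priors = NULL) {
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(ll), length(ll)), names(ll))
  }
  stopifnot(all(is.finite(ll)), abs(sum(priors) - 1) < 1e-8)
  if (!is.null(names(ll))) priors <- priors[names(ll)]
  z <- ll + log(priors)
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Fit the Word2Vec inversion classifier
#'
#' The inversion method: train one base skip-gram model on all training
#' sentences, then fine-tune a copy on each class's sentences, giving one
#' highly specialised language model per phenotype. A new document is
#' scored sentence by sentence: each sentence is assigned to the class
#' whose model gives it the higher (length-normalised) log-likelihood plus
#' log prior, and the patient's label is the majority vote over sentences.
#'
#' @param documents List of `patient_document` objects with stemmed
#'   sentences (see [aggregate_notes()] with `stem = TRUE`).
#' @param labels Character vector of `"SLE"`/`"CONTROL"`, one per document.
#' @param config An [embedding_config()].
#' @param normalize_ll If `TRUE` (default) each sentence log-likelihood is
#'   divided by its number of scored skip-gram pairs before class
#'   comparison, making the sentence decision length-invariant.
#' @param aggregate `"vote"` (majority vote over sentence labels, the
#'   study's rule) or `"sumll"` (sum of per-sentence log-likelihood margins,
#'   a labelled alternative).
#' @param priors `"empirical"` (training class frequencies) or a named
#'   numeric vector.
#' @return A `w2v_inversion` model object.
#' @export
w2v_inversion <- function(documents, labels, config = embedding_config(),
                          normalize_ll = TRUE,
                          aggregate = c("vote", "sumll"),
                          priors = "empirical") {
  aggregate <- match.arg(aggregate)
  labels <- as.character(labels)
  stopifnot(length(documents) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  all_sent <- unlist(lapply(documents, `[[`, "sentences"), recursive = FALSE)
  base <- train_base(all_sent, config)
  class_models <- list()
  for (i in seq_along(classes)) {
    cls_sent <- unlist(lapply(documents[labels == classes[i]], `[[`,
                              "sentences"), recursive = FALSE)
    class_models[[classes[i]]] <-
      finetune_embedding(base, cls_sent,
                         seed = derive_seed(config$seed, i))
  }
  pr <- if (identical(priors, "empirical")) {
    tab <- table(factor(labels, levels = classes))
    stats::setNames(as.numeric(tab) / sum(tab), classes)
  } else {
    stopifnot(is.numeric(priors), !is.null(names(priors)),
              setequal(names(priors), classes))
    priors[classes] / sum(priors)
  }
  structure(
    list(base = base, class_models = class_models, priors = pr,
         classes = classes, config = config, normalize_ll = normalize_ll,
         aggregate = aggregate),
    class = "w2v_inversion"
  )
}

#' @export
print.w2v_inversion <- function(x, ...) {
  cat(sprintf(
    "<w2v_inversion> classes: %s | priors: %s | d = %d, window = %d\n",
    paste(x$classes, collapse = "/"),
    paste(sprintf("%.3f", x$priors), collapse = "/"),
    x$config$dimension, x$config$window))
  invisible(x)
}

#' @export
summary.w2v_inversion <- function(object, ...) {
  cat("Word2Vec Bayesian inversion classifier\n")
  cat(sprintf("  vocabulary: %d words (min_count = %d)\n",
              nrow(object$base$vocab), object$config$min_count))
  cat(sprintf("  embedding: d = %d, window = %d, epochs = %d + %d\n",
              object$config$dimension, object$config$window,
              object$config$epochs_base, object$config$epochs_finetune))
  cat(sprintf("  classes: %s, priors %s\n",
              paste(object$classes, collapse = ", "),
              paste(sprintf("%.3f", object$priors), collapse = ", ")))
  cat(sprintf("  sentence aggregation: %s (%s log-likelihoods)\n",
              object$aggregate,
              if (object$normalize_ll) "pair-normalised" else "raw"))
  invisible(object)
}

# Per-sentence scores for one document: matrix with one row per sentence
# and one column per class (normalised ll + log prior), plus vote.
score_sentences <- function(inv, document) {
  sents <- document$sentences
  out <- matrix(NA_real_, nrow = length(sents), ncol = length(inv$classes),
                dimnames = list(NULL, inv$classes))
  pairs <- integer(length(sents))
  for (i in seq_along(sents)) {
    for (cls in inv$classes) {
      sc <- sentence_loglik(inv$class_models[[cls]], sents[[i]])
      if (!is.na(sc$ll)) {
        ll <- if (inv$normalize_ll) sc$ll / sc$n_pairs else sc$ll
        out[i, cls] <- ll + log(inv$priors[[cls]])
        pairs[i] <- sc$n_pairs
      }
    }
  }
  list(scores = out, n_pairs = pairs)
}

#' Classify one patient document by sentence-level inversion
#'
#' Each scoreable sentence votes for the class whose fine-tuned model gives
#' it the higher normalised log-likelihood plus log prior; the patient's
#' label is the most represented vote, with ties broken by the larger total
#' log-likelihood margin. The patient score is the fraction of sentences
#' voting SLE (used for ROC curves). A document with no scoreable sentence
#' abstains with score 0.5.
#'
#' @param inv A fitted [w2v_inversion()] model.
#' @param document A `patient_document` with stemmed sentences.
#' @return One-row data.frame: `patient_id`, `label`, `score`,
#'   `n_sentences` (scoreable sentences).
#' @export
classify_patient <- function(inv, document) {
  stopifnot(inherits(inv, "w2v_inversion"))
  sc <- score_sentences(inv, document)
  scores <- sc$scores[stats::complete.cases(sc$scores), , drop = FALSE]
  if (nrow(scores) == 0L) {
    return(data.frame(patient_id = document$patient_id, label = "ABSTAIN",
                      score = 0.5, n_sentences = 0L,
                      stringsAsFactors = FALSE))
  }
  votes <- inv$classes[max.col(scores, ties.method = "first")]
  if (inv$aggregate == "vote") {
    tab <- table(factor(votes, levels = inv$classes))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      # tie: larger summed margin towards each class decides
      margin <- colSums(scores - rowMeans(scores))
      top <- names(which.max(margin[top]))
    }
    label <- top[[1L]]
  } else {
    margin <- colSums(scores)
    label <- names(which.max(margin))
  }
  score_sle <- if ("SLE" %in% inv$classes) mean(votes == "SLE") else NA_real_
  data.frame(patient_id = document$patient_id, label = label,
             score = score_sle, n_sentences = nrow(scores),
             stringsAsFactors = FALSE)
}

#' Predict labels for documents with a fitted inversion model
#'
#' @param object A `w2v_inversion` model.
#' @param newdata List of `patient_document` objects (stemmed sentences).
#' @param ... Unused.
#' @return data.frame with one row per document: `patient_id`, `label`,
#'   `score` (fraction of sentences voting SLE), `n_sentences`.
#' @export
predict.w2v_inversion <- function(object, newdata, ...) {
  out <- lapply(newdata, classify_patient, inv = object)
  do.call(rbind, out)
}
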
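# Feature engineering: sparse bag-of-words term-frequency matrices,
# negation-aware concept frequency matrices from a dictionary lookup
# (the stand-in for a UMLS/CUI pipeline), L1 row normalisation, and
# Gini-importance feature selection down to a fixed subset.

#' Feature matrix container
#'
#' Thin S3 wrapper around a patients x features numeric matrix with the
#' normalisation state tracked explicitly. Raw bag-of-words cells are
#' non-negative counts; concept cells are integers that may be negative
#' through negation decrements.
#'
#' @param values Numeric matrix or `Matrix::sparseMatrix` with rownames
#'   (patient ids) and colnames (feature names, unique).
#' @param type `"bow"` or `"concept"`.
#' @param normalized Logical normalisation state.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, type = c("bow", "concept"),
                           normalized = FALSE) {
  type <- match.arg(type)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs row and column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature names", call. = FALSE)
  }
  structure(list(values = values, type = type, normalized = normalized),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d %s features (%s)\n",
              nrow(x$values), ncol(x$values), x$type,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Bag-of-words term-frequency matrix
#'
#' Counts Porter2 stems per patient document. The vocabulary is fitted on
#' the supplied documents unless `vocabulary` is given (pass the training
#' vocabulary when transforming validation/test documents; out-of-vocabulary
#' stems are ignored). Stems occurring in fewer than `min_doc_count`
#' fitting documents are dropped to control matrix width.
#'
#' @param documents List of `patient_document` objects.
#' @param vocabulary Optional character vector of stems fixing the feature
#'   space (no refitting).
#' @param stopword_list Stop words removed before stemming.
#' @param min_doc_count Document-frequency pruning threshold when fitting.
#' @return A sparse `feature_matrix` of type `"bow"`.
#' @export
bow_matrix <- function(documents, vocabulary = NULL,
                       stopword_list = stopwords_en(), min_doc_count = 2L) {
  stems <- lapply(documents, function(d) {
    preprocess_tokens(d$text, stopword_list)
  })
  ids <- vapply(documents, `[[`, character(1), "patient_id")
  if (is.null(vocabulary)) {
    df_counts <- table(unlist(lapply(stems, unique), use.names = FALSE))
    vocabulary <- sort(names(df_counts)[df_counts >= min_doc_count])
    if (!length(vocabulary)) {
      stop("empty vocabulary after pruning", call. = FALSE)
    }
  }
  triplets <- lapply(seq_along(stems), function(i) {
    tok <- stems[[i]]
    tok <- tok[tok %in% vocabulary]
    if (!length(tok)) return(NULL)
    tab <- table(tok)
    cbind(i = i, j = match(names(tab), vocabulary), x = as.integer(tab))
  })
  trip <- do.call(rbind, triplets)
  m <- Matrix::sparseMatrix(
    i = if (is.null(trip)) integer(0) else trip[, "i"],
    j = if (is.null(trip)) integer(0) else trip[, "j"],
    x = if (is.null(trip)) numeric(0) else trip[, "x"],
    dims = c(length(documents), length(vocabulary)),
    dimnames = list(ids, vocabulary)
  )
  feature_matrix(m, type = "bow", normalized = FALSE)
}

#' Concept dictionary
#'
#' Maps concept ids to lower-cased surface forms. A surface form may map to
#' several concepts (ambiguity); every concept needs at least one form.
#'
#' @param entries Named list: concept id -> character vector of forms.
#' @return A `concept_dictionary` object.
#' @export
concept_dictionary <- function(entries) {
  if (!length(entries) || is.null(names(entries))) {
    stop("`entries` must be a non-empty named list", call. = FALSE)
  }
  entries <- lapply(entries, function(f) unique(tolower(f)))
  if (any(lengths(entries) == 0L)) {
    stop("every concept needs at least one surface form", call. = FALSE)
  }
  structure(entries, class = "concept_dictionary")
}

#' @export
print.concept_dictionary <- function(x, ...) {
  cat(sprintf("<concept_dictionary> %d concepts, %d surface forms\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

# form -> token sequence and form -> concepts lookup tables
dictionary_index <- function(dictionary) {
  forms <- unique(unlist(dictionary, use.names = FALSE))
  form_tokens <- lapply(forms, tokenize_words)
  keep <- lengths(form_tokens) > 0L
  forms <- forms[keep]
  form_tokens <- form_tokens[keep]
  keys <- vapply(form_tokens, paste, character(1), collapse = " ")
  concepts <- lapply(keys, function(k) {
    names(dictionary)[vapply(dictionary, function(fs) {
      any(vapply(fs, function(f) {
        paste(tokenize_words(f), collapse = " ") == k
      }, logical(1)))
    }, logical(1))]
  })
  list(keys = keys, lengths = lengths(form_tokens), concepts = concepts)
}

#' Negation-aware concept frequency matrix
#'
#' Dictionary lookup over case-folded sentence tokens with longest-match,
#' leftmost-first resolution: at each position the longest matching surface
#' form wins and its span is consumed, so `"lupus nephritis"` increments the
#' nephritis concept without also incrementing the plain lupus concept. A
#' match increments every concept its surface form maps to (ambiguous
#' abbreviations deliberately double-count, reproducing the CUI ambiguity
#' failure mode), by +1 normally and by -1 when a negation cue occurs in the
#' same sentence at most `window` tokens before the match.
#'
#' @param documents List of `patient_document` objects (raw, unstemmed
#'   sentences).
#' @param dictionary A [concept_dictionary()].
#' @param cues Negation cue tokens ([negation_cues()] by default).
#' @param window Maximum token distance between cue and mention (same
#'   sentence), the classic NegEx-style default of 5.
#' @return A `feature_matrix` of type `"concept"` (dense integer matrix).
#' @export
concept_matrix <- function(documents, dictionary = default_concept_dictionary(),
                           cues = negation_cues(), window = 5L) {
  stopifnot(inherits(dictionary, "concept_dictionary"))
  idx <- dictionary_index(dictionary)
  max_len <- max(idx$lengths)
  concepts <- names(dictionary)
  ids <- vapply(documents, `[[`, character(1), "patient_id")
  m <- matrix(0L, nrow = length(documents), ncol = length(concepts),
              dimnames = list(ids, concepts))
  key_env <- new.env(parent = emptyenv())
  for (f in seq_along(idx$keys)) assign(idx$keys[f], f, envir = key_env)
  for (di in seq_along(documents)) {
    for (sent in documents[[di]]$sentences) {
      n <- length(sent)
      i <- 1L
      while (i <= n) {
        hit <- 0L
        for (len in seq(min(max_len, n - i + 1L), 1L)) {
          key <- paste(sent[i:(i + len - 1L)], collapse = " ")
          f <- get0(key, envir = key_env)
          if (!is.null(f)) {
            hit <- len
            neg <- any(sent[max(1L, i - window):max(1L, i - 1L)] %in% cues) &&
              i > 1L
            delta <- if (neg) -1L else 1L
            for (cid in idx$concepts[[f]]) {
              m[di, cid] <- m[di, cid] + delta
            }
            break
          }
        }
        i <- i + max(hit, 1L)
      }
    }
  }
  feature_matrix(m, type = "concept", normalized = FALSE)
}

#' L1 row normalisation
#'
#' Scales each patient row to relative frequencies (row sums to 1 in
#' absolute value); all-zero rows are left as zeros with a warning.
#' Normalising an already-normalised matrix is an error.
#'
#' @param matrix A raw `feature_matrix`.
#' @return The normalised `feature_matrix`.
#' @export
normalize_features <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$normalized) {
    stop("matrix is already normalized", call. = FALSE)
  }
  rs <- Matrix::rowSums(abs(matrix$values))
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) left unnormalized: ",
            paste(utils::head(rownames(matrix$values)[zero], 5),
                  collapse = ", "), call. = FALSE)
    rs[zero] <- 1
  }
  matrix$values <- matrix$values / rs
  matrix$normalized <- TRUE
  matrix
}

#' Gini-importance feature selection
#'
#' Ranks features by mean Gini impurity decrease in a 300-tree randomized
#' ensemble (ranger) fitted on the supplied rows only — inside a
#' cross-validation fold that must be the fold's training portion.
#' Importances are normalised to sum to 1; ties are broken
#' lexicographically by feature name for determinism. The matrix is
#' restricted to the top `k` features.
#'
#' @param matrix A `feature_matrix`.
#' @param labels `"SLE"`/`"CONTROL"` labels aligned with the rows.
#' @param k Number of features to retain (study default 100). If
#'   `k >= n_features` the matrix is returned unchanged with a warning.
#' @param n_trees Trees in the importance ensemble.
#' @param seed Integer seed.
#' @return List with `matrix` (restricted `feature_matrix`) and `ranking`
#'   (data.frame `rank`, `feature`, `vimp`, all features, descending).
#' @export
select_features <- function(matrix, labels, k = 100L, n_trees = 300L,
                            seed = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  y <- as_label_factor(labels)
  x <- as.matrix(matrix$values)
  if (nrow(x) != length(y)) stop("rows and labels misaligned", call. = FALSE)
  feats <- colnames(x)
  colnames(x) <- sprintf("f%06d", seq_along(feats))
  fit <- ranger::ranger(
    x = x, y = y, num.trees = n_trees, importance = "impurity",
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = TRUE
  )
  imp <- fit$variable.importance[colnames(x)]
  imp[is.na(imp) | imp < 0] <- 0
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, feats)
  ranking <- data.frame(rank = seq_along(feats), feature = feats[ord],
                        vimp = unname(imp[ord]), stringsAsFactors = FALSE)
  if (k >= length(feats)) {
    if (k > length(feats)) {
      warning("k exceeds the number of features; retaining all",
              call. = FALSE)
    }
    return(list(matrix = matrix, ranking = ranking))
  }
  keep <- sort(ranking$feature[seq_len(k)])
  matrix$values <- matrix$values[, keep, drop = FALSE]
  list(matrix = matrix, ranking = ranking)
}

#' Write a feature matrix in MatrixMarket format
#'
#' Writes `<prefix>.mtx` (sparse MatrixMarket) with sidecars
#' `<prefix>_features.txt` and `<prefix>_rows.txt`.
#'
#' @param matrix A `feature_matrix`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(matrix, dir, prefix = matrix$type) {
  stopifnot(inherits(matrix, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(matrix$values, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, paste0(prefix, ".mtx")))
  writeLines(colnames(matrix$values),
             file.path(dir, paste0(prefix, "_features.txt")))
  writeLines(rownames(matrix$values),
             file.path(dir, paste0(prefix, "_rows.txt")))
  invisible(dir)
}

#' Write an importance ranking as CSV
#'
#' @param ranking The `ranking` data.frame from [select_features()].
#' @param path Output CSV path (columns rank, feature, vimp).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}
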
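# Corpus preparation: keep rheumatology-relevant notes, aggregate each
# patient's retained notes into one patient-centric document, reserve an
# external test set, and balance classes by bootstrap resampling of the
# minority class. Fixed order of operations: filter -> holdout split ->
# balance within partitions.

#' Filter a patient's notes by keyword stem
#'
#' Retains exactly the notes whose case-folded text contains `keyword_stem`
#' as a substring (default `"rheumatol"`, which matches "Rheumatology",
#' "rheumatologist", ...). The match is on note text, not note-type tags.
#' A patient left with zero notes is returned with an empty note table and
#' must be recorded by the caller (see [filter_cohort()]), never silently
#' dropped.
#'
#' @param patient A `patient_record`.
#' @param keyword_stem Non-empty string.
#' @return The patient record with only matching notes retained.
#' @export
filter_notes <- function(patient, keyword_stem = "rheumatol") {
  stopifnot(inherits(patient, "patient_record"))
  if (!is.character(keyword_stem) || length(keyword_stem) != 1L ||
      !nzchar(keyword_stem)) {
    stop("`keyword_stem` must be a non-empty string", call. = FALSE)
  }
  keep <- grepl(tolower(keyword_stem), tolower(patient$notes$text),
                fixed = TRUE)
  patient$notes <- patient$notes[keep, , drop = FALSE]
  rownames(patient$notes) <- NULL
  patient
}

#' Filter every patient in a cohort
#'
#' Applies [filter_notes()] to each patient. Patients with no retained notes
#' are moved out of the active patient list and appended to the cohort's
#' exclusion log (`cohort$exclusions`).
#'
#' @param cohort A `pheno_cohort`.
#' @param keyword_stem Passed to [filter_notes()].
#' @return The filtered cohort.
#' @export
filter_cohort <- function(cohort, keyword_stem = "rheumatol") {
  stopifnot(inherits(cohort, "pheno_cohort"))
  filtered <- lapply(cohort$patients, filter_notes, keyword_stem = keyword_stem)
  empty <- vapply(filtered, function(p) nrow(p$notes) == 0L, logical(1))
  if (any(empty)) {
    ids <- vapply(filtered[empty], `[[`, character(1), "patient_id")
    cohort$exclusions <- c(cohort$exclusions,
                           sprintf("%s: no notes matching '%s'", ids,
                                   keyword_stem))
  }
  cohort$patients <- filtered[!empty]
  cohort
}

#' Aggregate a patient's notes into one document
#'
#' Concatenates the retained notes (in stored order, single-space
#' separator) and segments the result into sentences: the text is split on
#' sentence terminators (`.`, `!`, `?`, newline) and each fragment is
#' whitespace-tokenised after case folding and punctuation stripping.
#' Empty fragments (consecutive terminators) are dropped.
#'
#' @param patient A `patient_record` with at least one note.
#' @param stem If `TRUE`, Porter2-stem the sentence tokens (the embedding
#'   inversion path uses stemming only — no stop-word or punctuation-token
#'   engineering beyond tokenisation).
#' @return A `patient_document`: list with `patient_id`, `text`,
#'   `sentences` (list of character token vectors).
#' @export
aggregate_notes <- function(patient, stem = FALSE) {
  stopifnot(inherits(patient, "patient_record"))
  if (nrow(patient$notes) < 1L) {
    stop("patient ", patient$patient_id, " has no retained notes",
         call. = FALSE)
  }
  text <- paste(patient$notes$text, collapse = " ")
  frags <- strsplit(text, "[.!?\n]+")[[1L]]
  sentences <- lapply(frags, tokenize_words)
  sentences <- sentences[lengths(sentences) > 0L]
  if (stem) sentences <- lapply(sentences, porter2_stem)
  structure(
    list(patient_id = patient$patient_id, text = text,
         sentences = sentences),
    class = "patient_document"
  )
}

#' @export
print.patient_document <- function(x, ...) {
  cat(sprintf("<patient_document> %s: %d sentences, %d chars\n",
              x$patient_id, length(x$sentences), nchar(x$text)))
  invisible(x)
}

#' Aggregate all patients of a cohort
#'
#' @param cohort A `pheno_cohort` (already filtered).
#' @param stem Passed to [aggregate_notes()].
#' @return Named list of `patient_document` (names = patient ids).
#' @export
aggregate_cohort <- function(cohort, stem = FALSE) {
  docs <- lapply(cohort$patients, aggregate_notes, stem = stem)
  names(docs) <- vapply(docs, `[[`, character(1), "patient_id")
  docs
}

#' Reserve an external test set
#'
#' Seed-reproducible, class-stratified selection of `n_test` patients as the
#' TEST partition (stratification keeps the TEST class mix proportional to
#' the cohort's, so the partition is class-balanced after
#' [balance_by_bootstrap()]). All remaining patients are TRAIN.
#'
#' @param cohort A `pheno_cohort`.
#' @param n_test Number of TEST patients; must be `< n_patients`.
#' @param seed Integer seed (defaults to the cohort config seed).
#' @return The cohort with `split` set (named `"TRAIN"`/`"TEST"` vector).
#' @export
holdout_split <- function(cohort, n_test = cohort$config$holdout,
                          seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "pheno_cohort"))
  n <- length(cohort$patients)
  n_test <- as.integer(n_test)
  if (n_test >= n) stop("`n_test` must be smaller than the cohort", call. = FALSE)
  labels <- cohort_labels(cohort)
  split <- stats::setNames(rep("TRAIN", n), names(labels))
  if (n_test > 0L) {
    test_ids <- with_seed(seed, {
      ids <- character(0)
      for (cls in pheno_levels()) {
        cls_ids <- names(labels)[labels == cls]
        take <- round(n_test * length(cls_ids) / n)
        ids <- c(ids, sample(cls_ids, min(take, length(cls_ids))))
      }
      # rounding can leave the total off by one; top up / trim at random
      pool <- setdiff(names(labels), ids)
      while (length(ids) < n_test) {
        extra <- sample(pool, 1)
        ids <- c(ids, extra)
        pool <- setdiff(pool, extra)
      }
      if (length(ids) > n_test) ids <- sample(ids, n_test)
      ids
    })
    split[test_ids] <- "TEST"
  }
  cohort$split <- split
  cohort
}

#' Balance classes by bootstrap resampling
#'
#' Within each partition (TRAIN and TEST independently; the whole cohort if
#' no split is set), the minority class is resampled with replacement until
#' class counts are equal. Duplicated patients share note text but receive
#' distinct suffixed ids (`<id>_b1`, `_b2`, ...), and a duplicate never
#' straddles the TRAIN/TEST boundary, so balancing cannot leak test
#' patients into training.
#'
#' @param cohort A `pheno_cohort`.
#' @param seed Integer seed (defaults to the cohort config seed).
#' @return The balanced cohort; duplicated records carry
#'   `is_bootstrap_duplicate = TRUE`.
#' @export
balance_by_bootstrap <- function(cohort, seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "pheno_cohort"))
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  split <- if (is.null(cohort$split)) {
    stats::setNames(rep("TRAIN", length(ids)), ids)
  } else {
    cohort$split
  }
  labels <- cohort_labels(cohort)
  balanced <- with_seed(seed, {
    new_patients <- list()
    new_split <- character(0)
    for (part in unique(split)) {
      part_ids <- names(split)[split == part]
      part_lab <- labels[part_ids]
      counts <- table(factor(part_lab, levels = pheno_levels()))
      if (any(counts == 0L)) {
        stop("partition ", part, " contains only one class", call. = FALSE)
      }
      minority <- names(counts)[which.min(counts)]
      deficit <- max(counts) - min(counts)
      keep <- cohort$patients[match(part_ids, ids)]
      if (deficit > 0L) {
        pool <- part_ids[part_lab == minority]
        picked <- sample(pool, deficit, replace = TRUE)
        dup <- lapply(seq_along(picked), function(j) {
          rec <- cohort$patients[[match(picked[j], ids)]]
          rec$source_id <- rec$patient_id
          rec$patient_id <- sprintf("%s_b%d", picked[j],
                                    sum(picked[seq_len(j)] == picked[j]))
          rec$is_bootstrap_duplicate <- TRUE
          rec
        })
        keep <- c(keep, dup)
      }
      new_patients <- c(new_patients, keep)
      part_new <- stats::setNames(
        rep(part, length(keep)),
        vapply(keep, `[[`, character(1), "patient_id"))
      new_split <- c(new_split, part_new)
    }
    list(patients = new_patients, split = new_split)
  })
  cohort$patients <- balanced$patients
  cohort$split <- balanced$split
  cohort
}

#' Write split assignments and the exclusion log
#'
#' Writes `splits.csv` (patient_id, partition, is_bootstrap_duplicate) and
#' `exclusions.log` to `dir`.
#'
#' @param cohort A `pheno_cohort` with a split assignment.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_splits <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pheno_cohort"), !is.null(cohort$split))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    partition = unname(cohort$split[vapply(cohort$patients, `[[`,
                                           character(1), "patient_id")]),
    is_bootstrap_duplicate = vapply(
      cohort$patients,
      function(p) isTRUE(p$is_bootstrap_duplicate), logical(1))
  )
  utils::write.csv(df, file.path(dir, "splits.csv"), row.names = FALSE)
  writeLines(cohort$exclusions, file.path(dir, "exclusions.log"))
  invisible(dir)
}
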
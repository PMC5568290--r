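# Note filtering, patient aggregation, holdout split and bootstrap
# balancing.

test_that("keyword filter retains exactly the matching notes", {
  p <- make_patient("P1", c("Seen in Rheumatology clinic.",
                            "dermatology follow-up",
                            "called RHEUMATOLOGIST about flare"))
  f <- filter_notes(p, "rheumatol")
  expect_identical(nrow(f$notes), 2L)
  expect_false(any(grepl("dermatology", f$notes$text)))
  expect_error(filter_notes(p, ""), "non-empty")
})

test_that("filtering is idempotent and empty patients go to the exclusion log", {
  p <- make_patient("P1", c("Rheumatology note.", "other note"))
  once <- filter_notes(p)
  expect_identical(filter_notes(once), once)

  coh <- structure(list(
    patients = list(make_patient("A", "rheumatology visit"),
                    make_patient("B", "podiatry visit")),
    config = synth_config(n_patients = 2, holdout = 0, seed = 1),
    split = NULL, exclusions = character(0)), class = "pheno_cohort")
  out <- filter_cohort(coh)
  expect_identical(length(out$patients), 1L)
  expect_match(out$exclusions, "^B:")
})

test_that("aggregation concatenates notes and segments sentences", {
  p <- make_patient("P1", c("A b.", "C d."))
  doc <- aggregate_notes(p)
  expect_identical(doc$text, "A b. C d.")
  expect_identical(length(doc$sentences), 2L)
  expect_identical(doc$sentences[[1]], c("a", "b"))

  one <- aggregate_notes(make_patient("P2", "Single note text."))
  expect_identical(one$text, "Single note text.")

  # consecutive terminators produce no empty sentences
  frag <- aggregate_notes(make_patient("P3", "First one... Second!! ?"))
  expect_identical(length(frag$sentences), 2L)

  stemmed <- aggregate_notes(make_patient("P4", "Fatigue resolved."),
                             stem = TRUE)
  expect_identical(stemmed$sentences[[1]], c("fatigu", "resolv"))
  expect_error(aggregate_notes(make_patient("P5", character(0))),
               "no retained notes")
})

test_that("holdout split is stratified, seed-stable and sized exactly", {
  coh <- small_cohort(n = 120, seed = 3, holdout = 40)
  s1 <- holdout_split(coh, n_test = 40, seed = 5)
  expect_identical(sum(s1$split == "TEST"), 40L)
  expect_identical(sum(s1$split == "TRAIN"), 80L)
  s2 <- holdout_split(coh, n_test = 40, seed = 5)
  expect_identical(s1$split, s2$split)
  # stratification: TEST class mix within rounding of the cohort's
  lab <- cohort_labels(coh)
  test_ids <- names(s1$split)[s1$split == "TEST"]
  expect_lt(abs(mean(lab[test_ids] == "SLE") - mean(lab == "SLE")), 0.05)
  s0 <- holdout_split(coh, n_test = 0)
  expect_true(all(s0$split == "TRAIN"))
  expect_error(holdout_split(coh, n_test = 120), "smaller")
})

test_that("bootstrap balancing equalises classes within every partition", {
  coh <- small_cohort(n = 80, seed = 13, holdout = 20)
  coh <- holdout_split(coh)
  bal <- balance_by_bootstrap(coh, seed = 21)
  lab <- cohort_labels(bal)
  for (part in c("TRAIN", "TEST")) {
    ids <- names(bal$split)[bal$split == part]
    counts <- table(lab[ids])
    expect_identical(unname(counts[["SLE"]]), unname(counts[["CONTROL"]]))
  }
  # duplicates stay inside their source partition
  dups <- Filter(function(p) isTRUE(p$is_bootstrap_duplicate), bal$patients)
  for (d in dups) {
    expect_identical(unname(bal$split[[d$patient_id]]),
                     unname(coh$split[[d$source_id]]))
  }
  # no TEST id or duplicate of one appears in TRAIN
  src <- vapply(bal$patients, function(p) {
    if (!is.null(p$source_id)) p$source_id else p$patient_id
  }, character(1))
  train_src <- src[bal$split == "TRAIN"]
  test_src <- src[bal$split == "TEST"]
  expect_length(intersect(train_src, test_src), 0L)
  # determinism
  expect_identical(balance_by_bootstrap(coh, seed = 21)$split, bal$split)
})

test_that("already balanced partitions pass through unchanged", {
  patients <- c(lapply(1:5, function(i) {
    make_patient(sprintf("S%d", i), "rheum note", label = "SLE")
  }), lapply(1:5, function(i) {
    make_patient(sprintf("C%d", i), "rheum note", label = "CONTROL")
  }))
  coh <- structure(list(patients = patients,
                        config = synth_config(n_patients = 10, holdout = 0,
                                              seed = 1),
                        split = NULL, exclusions = character(0)),
                   class = "pheno_cohort")
  bal <- balance_by_bootstrap(coh, seed = 1)
  expect_identical(length(bal$patients), 10L)
  expect_false(any(vapply(bal$patients,
                          function(p) isTRUE(p$is_bootstrap_duplicate),
                          logical(1))))
  # single-class partition is an error
  coh$patients <- patients[1:5]
  expect_error(balance_by_bootstrap(coh, seed = 1), "one class")
})
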
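# Synthetic cohort generator: classification rule, class mix, determinism,
# and the nuisance-rate contracts.

test_that("ACR/SLICC rule labels the worked profiles correctly", {
  expect_identical(label_from_criteria(criterion_profile(c(1, 3, 5, 11))),
                   "SLE")
  expect_identical(label_from_criteria(criterion_profile()), "CONTROL")
  expect_identical(
    label_from_criteria(criterion_profile(c(7, 11),
                                          has_lupus_nephritis = TRUE,
                                          has_ana_or_dsdna = TRUE)),
    "SLE")
  expect_identical(label_from_criteria(criterion_profile(c(1, 2, 3))),
                   "CONTROL")
})

test_that("invalid profiles are rejected", {
  expect_error(criterion_profile(c(0, 5)), "1..11")
  expect_error(criterion_profile(12), "1..11")
  expect_error(criterion_profile(c(1, 2), has_lupus_nephritis = TRUE),
               "criterion 7")
})

test_that("a fixed seed makes the whole cohort byte-identical", {
  cfg <- synth_config(n_patients = 15, holdout = 5, seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  p1 <- sample_profile(cfg)
  p2 <- sample_profile(cfg)
  expect_identical(p1, p2)
})

test_that("empirical SLE fraction converges to sle_fraction", {
  cfg <- synth_config(n_patients = 1000, holdout = 100, seed = 3)
  lab <- cohort_labels(generate_cohort(cfg))
  p <- cfg$sle_fraction
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(mean(lab == "SLE") - p), 3 * se)
  cfg1 <- synth_config(n_patients = 50, holdout = 0, sle_fraction = 0.999,
                       seed = 4)
  expect_true(all(cohort_labels(generate_cohort(cfg1)) == "SLE"))
})

test_that("nuisance rates at zero remove their artifacts from the text", {
  cfg <- synth_config(n_patients = 40, holdout = 0,
                      negated_mention_rate = 0, ambiguous_abbrev_rate = 0,
                      artifact_token_rate = 0, seed = 11)
  coh <- generate_cohort(cfg)
  all_text <- tolower(paste(unlist(lapply(coh$patients,
                                          function(p) p$notes$text)),
                            collapse = " "))
  toks <- tokenize_words(all_text)
  expect_false(any(negation_cues() %in% toks))
  expect_false(any(c("sle", "er") %in% toks))
  expect_false(any(grepl("843identificationremov|authid", all_text)))
})

test_that("every patient keeps at least one rheumatology note", {
  coh <- small_cohort(n = 30, seed = 9)
  hits <- vapply(coh$patients, function(p) {
    any(grepl("rheumatol", tolower(p$notes$text), fixed = TRUE))
  }, logical(1))
  expect_true(all(hits))
})

test_that("held criteria surface as lexicon phrases in the notes", {
  cfg <- synth_config(n_patients = 10, holdout = 0,
                      criterion_mention_rate = 1, negated_mention_rate = 0,
                      seed = 13)
  prof <- criterion_profile(c(1, 5, 9, 11))
  notes <- generate_notes(prof, cfg, seed = 21)
  text <- tolower(paste(notes$text, collapse = " "))
  ana_phrases <- criterion_lexicon()[["11"]]
  expect_true(any(vapply(ana_phrases, grepl, logical(1), x = text,
                         fixed = TRUE)))
})

test_that("ICD-9 coding follows the configured error rates", {
  cfg <- synth_config(n_patients = 10, holdout = 0, icd9_sensitivity = 1,
                      icd9_specificity = 1, seed = 5)
  expect_true("710.0" %in% assign_icd9("SLE", cfg, seed = 1))
  expect_false("710.0" %in% assign_icd9("CONTROL", cfg, seed = 1))
  # sens = spec = 0.5 makes the hard rule uninformative: AUC of a 0/1 rule
  # is (sens + spec) / 2
  cfg5 <- synth_config(n_patients = 10, holdout = 0, icd9_sensitivity = 0.5,
                       icd9_specificity = 0.5, seed = 5)
  hits <- vapply(1:400, function(i) {
    lab <- if (i %% 2 == 0) "SLE" else "CONTROL"
    has <- "710.0" %in% assign_icd9(lab, cfg5, seed = i)
    auc_contrib <- (lab == "SLE") == has
    auc_contrib
  }, logical(1))
  sens_plus_spec <- mean(hits[seq(2, 400, 2)]) + mean(hits[seq(1, 399, 2)])
  expect_lt(abs(sens_plus_spec / 2 - 0.5), 3 * 0.025)
})

test_that("cohort writer produces the documented file layout", {
  coh <- small_cohort(n = 4, seed = 2, holdout = 0)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "criteria.csv")))
  df <- read.csv(file.path(dir, "cohort.csv"))
  expect_identical(nrow(df), 4L)
  first <- coh$patients[[1]]
  expect_true(file.exists(file.path(dir, paste0(first$patient_id, "_1.txt"))))
})

test_that("config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 12", "holdout: 4", "seed: 99"), path)
  cfg <- synth_config_from_file(path)
  expect_identical(cfg$n_patients, 12L)
  expect_identical(cfg$seed, 99L)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_patients: 12", path2)
  expect_error(synth_config_from_file(path2), "seed")
})

test_that("planted-signal corpus has disjoint class vocabularies", {
  corp <- simulate_inversion_corpus(n_patients = 20, seed = 8)
  toks_by_class <- lapply(split(corp$documents, corp$labels), function(ds) {
    unique(unlist(lapply(ds, `[[`, "sentences")))
  })
  sig_sle <- grep("^nephropathi", toks_by_class$SLE, value = TRUE)
  sig_ctl <- grep("^osteopathi", toks_by_class$CONTROL, value = TRUE)
  expect_gt(length(sig_sle), 0)
  expect_gt(length(sig_ctl), 0)
  expect_false(any(grepl("^osteopathi", toks_by_class$SLE)))
  expect_false(any(grepl("^nephropathi", toks_by_class$CONTROL)))
  expect_identical(simulate_inversion_corpus(n_patients = 20, seed = 8),
                   corp)
  null_corp <- simulate_inversion_corpus(n_patients = 20, seed = 8,
                                         null = TRUE)
  expect_false(any(grepl("pathi", unlist(lapply(null_corp$documents,
                                                `[[`, "sentences")))))
})
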
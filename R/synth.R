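# Synthetic EHR corpus generator. Emulates the statistical structure the
# phenotyping analysis assumes: per-patient multi-note corpora in which only
# a fraction of notes are rheumatology-relevant, class-correlated criterion
# vocabulary, negated mentions, ambiguous abbreviations ("SLE", "ER"),
# site-specific artifact tokens, and ICD-9 code 710.0 assigned with
# configurable sensitivity/specificity. Ground truth comes from the
# ACR/SLICC classification rule, not from the text, so the text signal and
# the label can be decoupled by the nuisance-rate knobs.

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic EHR generator. Defaults mirror the shape of
#' the rheumatology study cohort the pipeline is designed around: 662
#' patients of whom 322 (48.6%) are SLE cases, a 100-patient external
#' holdout, and ICD-9 coding with 90% sensitivity and specificity so that
#' the rule-based ICD-9 baseline lands near 90% accuracy / 0.90 AUC on
#' balanced data.
#'
#' @param n_patients Number of patients (>= 2).
#' @param sle_fraction Expected proportion of SLE cases, in (0, 1).
#' @param notes_min,notes_max Per-patient note count is drawn uniformly from
#'   `notes_min:notes_max`. The real per-patient distribution is not public;
#'   these defaults are an arbitrary but fixed choice (see vignette).
#' @param rheum_note_fraction Probability that a note is a rheumatology note
#'   (contains the substring `"rheumatol"`); at least one rheumatology note
#'   per patient is always emitted so no patient is vacuously filtered out.
#' @param criterion_mention_rate Per-rheumatology-note probability that each
#'   held criterion is mentioned.
#' @param negated_mention_rate Proportion of criterion mentions wrapped in a
#'   negation template; also the per-note rate of negated mentions of
#'   criteria the patient does not have.
#' @param ambiguous_abbrev_rate Per-note rate of ambiguous-abbreviation
#'   sentences ("SLE" as diagnosis vs. arbovirus context, "ER").
#' @param artifact_token_rate Per-note rate of site-specific artifact tokens
#'   for SLE patients (controls get one quarter of the rate, making the
#'   artifact a class-skewed confounder).
#' @param icd9_sensitivity,icd9_specificity Probability that an SLE patient
#'   carries code 710.0, and that a control does not.
#' @param holdout Number of patients reserved for the external test set.
#' @param seed Integer seed; mandatory, fully determines the cohort.
#' @return A `synth_config` object (validated list).
#' @export
synth_config <- function(n_patients = 662L,
                         sle_fraction = 322 / 662,
                         notes_min = 4L,
                         notes_max = 12L,
                         rheum_note_fraction = 0.4,
                         criterion_mention_rate = 0.6,
                         negated_mention_rate = 0.15,
                         ambiguous_abbrev_rate = 0.10,
                         artifact_token_rate = 0.05,
                         icd9_sensitivity = 0.9,
                         icd9_specificity = 0.9,
                         holdout = 100L,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory in synth_config()", call. = FALSE)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop("`n_patients` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sle_fraction) || sle_fraction <= 0 || sle_fraction >= 1) {
    stop("`sle_fraction` must lie in (0, 1)", call. = FALSE)
  }
  notes_min <- as.integer(notes_min)
  notes_max <- as.integer(notes_max)
  if (notes_min < 1L || notes_min > notes_max) {
    stop("need 1 <= notes_min <= notes_max", call. = FALSE)
  }
  for (nm in c("rheum_note_fraction", "criterion_mention_rate",
               "negated_mention_rate", "ambiguous_abbrev_rate",
               "artifact_token_rate", "icd9_sensitivity",
               "icd9_specificity")) {
    stopifnot_proportion(get(nm), nm)
  }
  holdout <- as.integer(holdout)
  if (holdout < 0L || holdout >= n_patients) {
    stop("`holdout` must be in [0, n_patients)", call. = FALSE)
  }
  structure(
    list(
      n_patients = n_patients, sle_fraction = sle_fraction,
      notes_min = notes_min, notes_max = notes_max,
      rheum_note_fraction = rheum_note_fraction,
      criterion_mention_rate = criterion_mention_rate,
      negated_mention_rate = negated_mention_rate,
      ambiguous_abbrev_rate = ambiguous_abbrev_rate,
      artifact_token_rate = artifact_token_rate,
      icd9_sensitivity = icd9_sensitivity,
      icd9_specificity = icd9_specificity,
      holdout = holdout, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Read a synthetic-cohort configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file whose keys are
#'   [synth_config()] arguments. `seed` must be present.
#' @return A `synth_config` object.
#' @export
synth_config_from_file <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed)) stop("config file must set `seed`", call. = FALSE)
  do.call(synth_config, vals)
}

#' Criterion profile
#'
#' The per-patient ground-truth state: which of the eleven ACR criteria are
#' met, plus the two SLICC flags (biopsy-proven lupus nephritis; ANA or
#' anti-dsDNA positivity). Nephritis implies renal disorder, so
#' `has_lupus_nephritis` requires criterion 7.
#'
#' @param criteria Integer vector, subset of 1..11 (may be empty).
#' @param has_lupus_nephritis,has_ana_or_dsdna Logical flags.
#' @return A `criterion_profile` object.
#' @export
criterion_profile <- function(criteria = integer(0),
                              has_lupus_nephritis = FALSE,
                              has_ana_or_dsdna = FALSE) {
  criteria <- sort(unique(as.integer(criteria)))
  if (length(criteria) && (any(is.na(criteria)) || any(criteria < 1L) ||
                           any(criteria > 11L))) {
    stop("criterion ids must lie in 1..11", call. = FALSE)
  }
  if (isTRUE(has_lupus_nephritis) && !(7L %in% criteria)) {
    stop("lupus nephritis requires renal disorder (criterion 7)",
         call. = FALSE)
  }
  structure(
    list(criteria = criteria,
         has_lupus_nephritis = isTRUE(has_lupus_nephritis),
         has_ana_or_dsdna = isTRUE(has_ana_or_dsdna)),
    class = "criterion_profile"
  )
}

#' Classify a criterion profile as SLE or control
#'
#' The classification rule: SLE requires at least four of the eleven ACR
#' criteria, or — the SLICC alternative — lupus nephritis as the sole
#' clinical criterion in the presence of ANA or anti-dsDNA antibodies.
#'
#' @param profile A [criterion_profile()].
#' @return `"SLE"` or `"CONTROL"`.
#' @examples
#' label_from_criteria(criterion_profile(c(1, 3, 5, 11)))
#' label_from_criteria(criterion_profile(c(7, 11), TRUE, TRUE))
#' @export
label_from_criteria <- function(profile) {
  if (!inherits(profile, "criterion_profile")) {
    stop("`profile` must be a criterion_profile", call. = FALSE)
  }
  if (length(profile$criteria) >= 4L ||
      (profile$has_lupus_nephritis && profile$has_ana_or_dsdna)) "SLE" else "CONTROL"
}

# Draw one criterion profile destined for the configured class mix. Uses the
# current RNG stream (callers wrap in with_seed).
sample_profile_impl <- function(config) {
  sle <- runif(1) < config$sle_fraction
  if (sle) {
    # 15% of cases arrive via the SLICC nephritis pathway with < 4 criteria
    if (runif(1) < 0.15) {
      extra <- sample(setdiff(1:11, 7L), sample(0:2, 1))
      criterion_profile(c(7L, extra), has_lupus_nephritis = TRUE,
                        has_ana_or_dsdna = TRUE)
    } else {
      k <- sample(4:7, 1)
      crit <- sort(sample(1:11, k))
      criterion_profile(
        crit,
        has_lupus_nephritis = (7L %in% crit) && runif(1) < 0.5,
        has_ana_or_dsdna = (11L %in% crit) || runif(1) < 0.5
      )
    }
  } else {
    k <- sample(0:3, 1)
    crit <- if (k > 0) sort(sample(1:11, k)) else integer(0)
    # controls never satisfy the SLICC pair
    criterion_profile(crit, has_lupus_nephritis = FALSE,
                      has_ana_or_dsdna = runif(1) < 0.2)
  }
}

#' Sample a criterion profile
#'
#' Draws a profile whose [label_from_criteria()] outcome is SLE with
#' probability `sle_fraction`: SLE-destined patients receive at least four
#' criteria or the SLICC nephritis/ANA pair, controls at most three criteria
#' and never the SLICC pair.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed for this draw (defaults to the config seed).
#' @return A `criterion_profile`.
#' @export
sample_profile <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, sample_profile_impl(config))
}

affirm_templates <- function() {
  c("exam notable for %s", "%s present today",
    "assessment consistent with %s", "findings include %s")
}

negate_templates <- function() {
  c("no evidence of %s", "denies %s", "no %s noted")
}

noise_sentence <- function() {
  paste(sample(background_vocabulary(), sample(5:9, 1), replace = TRUE),
        collapse = " ")
}

artifact_tokens <- function() c("843identificationremov", "authid4437")

# One rheumatology note for a profile; returns a single string with
# period-delimited sentences.
rheum_note_text <- function(profile, label, config) {
  lex <- criterion_lexicon()
  sent <- c(sample(c("seen in rheumatology clinic today",
                     "rheumatology followup visit"), 1))
  for (cid in profile$criteria) {
    if (runif(1) < config$criterion_mention_rate) {
      phrase <- sample(lex[[as.character(cid)]], 1)
      tmpl <- if (runif(1) < config$negated_mention_rate) {
        sample(negate_templates(), 1)
      } else {
        sample(affirm_templates(), 1)
      }
      sent <- c(sent, sprintf(tmpl, phrase))
    }
  }
  # negated mention of a criterion the patient does not have
  absent <- setdiff(1:11, profile$criteria)
  if (length(absent) && runif(1) < config$negated_mention_rate) {
    phrase <- sample(lex[[as.character(sample(absent, 1))]], 1)
    sent <- c(sent, sprintf(sample(negate_templates(), 1), phrase))
  }
  if (runif(1) < config$ambiguous_abbrev_rate) {
    sent <- c(sent, if (label == "SLE") {
      sample(c("sle flare discussed with patient",
               "longstanding sle followed in clinic"), 1)
    } else {
      sample(ambiguous_templates(), 1)
    })
  }
  art_rate <- if (label == "SLE") config$artifact_token_rate else config$artifact_token_rate / 4
  if (runif(1) < art_rate) {
    sent <- c(sent, paste("note reviewed", sample(artifact_tokens(), 1)))
  }
  sent <- c(sent, replicate(sample(2:4, 1), noise_sentence()))
  paste0(paste(sent, collapse = ". "), ".")
}

noise_note_text <- function() {
  sent <- c(sample(c("dermatology followup", "primary care visit",
                     "lab visit for routine monitoring",
                     "radiology report reviewed"), 1),
            replicate(sample(2:5, 1), noise_sentence()))
  paste0(paste(sent, collapse = ". "), ".")
}

#' Generate the notes for one patient
#'
#' Emits `notes_min:notes_max` notes of which a `rheum_note_fraction` share
#' (at least one) contain the substring `"rheumatol"` and carry the
#' criterion-phrase signal; the remainder are class-independent noise notes.
#' Criterion mentions come from the fixed [criterion_lexicon()]; a
#' `negated_mention_rate` share are wrapped in negation templates; ambiguous
#' abbreviations and artifact tokens are injected at the configured rates.
#'
#' @param profile A [criterion_profile()].
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return data.frame with columns `note_type`, `text`.
#' @export
generate_notes <- function(profile, config, seed = config$seed) {
  stopifnot(inherits(profile, "criterion_profile"),
            inherits(config, "synth_config"))
  if (!length(criterion_lexicon())) stop("empty criterion lexicon", call. = FALSE)
  label <- label_from_criteria(profile)
  with_seed(seed, {
    n_notes <- sample(config$notes_min:config$notes_max, 1)
    is_rheum <- runif(n_notes) < config$rheum_note_fraction
    if (!any(is_rheum)) is_rheum[sample(n_notes, 1)] <- TRUE
    text <- character(n_notes)
    type <- character(n_notes)
    for (i in seq_len(n_notes)) {
      if (is_rheum[i]) {
        type[i] <- "progress"
        text[i] <- rheum_note_text(profile, label, config)
      } else {
        type[i] <- sample(c("lab", "radiology", "primary care"), 1)
        text[i] <- noise_note_text()
      }
    }
    data.frame(note_type = type, text = text, stringsAsFactors = FALSE)
  })
}

#' Assign ICD-9 codes
#'
#' SLE patients carry code `"710.0"` with probability `icd9_sensitivity`;
#' controls carry it with probability `1 - icd9_specificity`. All patients
#' may carry irrelevant filler codes.
#'
#' @param gold_label `"SLE"` or `"CONTROL"`.
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return Character vector of ICD-9 code strings.
#' @export
assign_icd9 <- function(gold_label, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  gold_label <- match.arg(gold_label, pheno_levels())
  with_seed(seed, {
    p <- if (gold_label == "SLE") config$icd9_sensitivity else 1 - config$icd9_specificity
    codes <- character(0)
    if (runif(1) < p) codes <- "710.0"
    filler <- c("401.9", "272.4", "244.9", "530.81", "285.9", "714.0")
    codes <- c(codes, sample(filler, sample(1:3, 1)))
    sample(codes) # order carries no meaning
  })
}

#' Generate a full synthetic cohort
#'
#' Draws `n_patients` patient records: criterion profile, ACR/SLICC gold
#' label, multi-note corpus, and ICD-9 codes. Byte-identical across runs
#' for a fixed config (including seed).
#'
#' @param config A [synth_config()].
#' @return A `pheno_cohort`: list with `patients` (list of `patient_record`)
#'   and `config`. Each `patient_record` has `patient_id`, `notes`
#'   (data.frame `note_type`, `text`), `icd9_codes`, `gold_label`,
#'   `profile`.
#' @examples
#' coh <- generate_cohort(synth_config(n_patients = 10, seed = 1))
#' table(cohort_labels(coh))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  width <- nchar(as.character(config$n_patients))
  patients <- with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) {
      profile <- sample_profile_impl(config)
      label <- label_from_criteria(profile)
      # per-patient sub-seeds keep records independent of generation order
      sub <- derive_seed(config$seed, i)
      rec <- list(
        patient_id = sprintf("P%0*d", width, i),
        notes = generate_notes(profile, config, seed = sub),
        icd9_codes = assign_icd9(label, config, seed = sub + 1),
        gold_label = label,
        profile = profile
      )
      class(rec) <- "patient_record"
      rec
    })
  })
  structure(list(patients = patients, config = config,
                 split = NULL, exclusions = character(0)),
            class = "pheno_cohort")
}

#' @export
print.pheno_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<pheno_cohort> %d patients (%d SLE / %d CONTROL), %d notes\n",
              length(x$patients), sum(lab == "SLE"), sum(lab == "CONTROL"),
              sum(vapply(x$patients, function(p) nrow(p$notes), integer(1)))))
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d TRAIN / %d TEST\n",
                sum(x$split == "TRAIN"), sum(x$split == "TEST")))
  }
  invisible(x)
}

#' Gold labels of a cohort
#' @param cohort A `pheno_cohort`.
#' @return Named character vector of `"SLE"`/`"CONTROL"`, names patient ids.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$patients, function(p) p$gold_label, character(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(cohort$patients, function(p) p$patient_id,
                           character(1)))
}

#' Write a cohort to disk
#'
#' One UTF-8 text file per note (`<patient_id>_<note_idx>.txt`) plus
#' `cohort.csv` (patient_id, gold_label, icd9_codes semicolon-joined,
#' n_notes) and `criteria.csv` (patient_id, criterion ids semicolon-joined,
#' SLICC flags).
#'
#' @param cohort A `pheno_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pheno_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    for (i in seq_len(nrow(p$notes))) {
      writeLines(p$notes$text[i],
                 file.path(dir, sprintf("%s_%d.txt", p$patient_id, i)),
                 useBytes = TRUE)
    }
  }
  cohort_df <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    gold_label = vapply(cohort$patients, `[[`, character(1), "gold_label"),
    icd9_codes = vapply(cohort$patients,
                        function(p) paste(p$icd9_codes, collapse = ";"),
                        character(1)),
    n_notes = vapply(cohort$patients, function(p) nrow(p$notes), integer(1))
  )
  utils::write.csv(cohort_df, file.path(dir, "cohort.csv"), row.names = FALSE)
  crit_df <- data.frame(
    patient_id = cohort_df$patient_id,
    criteria = vapply(cohort$patients,
                      function(p) paste(p$profile$criteria, collapse = ";"),
                      character(1)),
    has_lupus_nephritis = vapply(cohort$patients,
                                 function(p) p$profile$has_lupus_nephritis,
                                 logical(1)),
    has_ana_or_dsdna = vapply(cohort$patients,
                              function(p) p$profile$has_ana_or_dsdna,
                              logical(1))
  )
  utils::write.csv(crit_df, file.path(dir, "criteria.csv"), row.names = FALSE)
  invisible(dir)
}

#' Planted-signal corpus for the inversion benchmark
#'
#' Generates tokenised patient documents for benchmarking the embedding
#' inversion classifier in isolation: every sentence is background
#' vocabulary; with probability `signal_rate` a sentence additionally
#' carries one token from its patient's class-specific vocabulary (the two
#' class vocabularies are disjoint). Under `null = TRUE` both classes draw
#' from the identical distribution, so no classifier can beat chance.
#'
#' @param n_patients Number of patients (balanced classes).
#' @param sentences_per_patient Sentences per patient document.
#' @param signal_rate Per-sentence probability of a class-token mention.
#' @param n_class_tokens Size of each class-specific vocabulary.
#' @param seed Integer seed.
#' @param null If `TRUE`, generate label-independent text (permutation-null
#'   analogue).
#' @return List with `documents` (list of `patient_document`) and `labels`.
#' @export
simulate_inversion_corpus <- function(n_patients = 200L,
                                      sentences_per_patient = 30L,
                                      signal_rate = 0.3,
                                      n_class_tokens = 5L,
                                      seed,
                                      null = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot_proportion(signal_rate, "signal_rate")
  bg <- background_vocabulary()
  sig <- list(
    SLE = sprintf("nephropathi%d", seq_len(n_class_tokens)),
    CONTROL = sprintf("osteopathi%d", seq_len(n_class_tokens))
  )
  with_seed(seed, {
    labels <- rep(pheno_levels(), length.out = n_patients)
    docs <- lapply(seq_len(n_patients), function(i) {
      sents <- lapply(seq_len(sentences_per_patient), function(j) {
        toks <- sample(bg, sample(6:10, 1), replace = TRUE)
        if (!null && runif(1) < signal_rate) {
          tok <- sample(sig[[labels[i]]], 1)
          pos <- sample(length(toks) + 1L, 1) - 1L
          toks <- append(toks, tok, after = pos)
        }
        toks
      })
      structure(
        list(patient_id = sprintf("S%03d", i),
             text = paste(vapply(sents, paste, character(1), collapse = " "),
                          collapse = ". "),
             sentences = sents),
        class = "patient_document"
      )
    })
    list(documents = docs, labels = labels)
  })
}
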
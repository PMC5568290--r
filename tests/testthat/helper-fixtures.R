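# Shared fixture builders: everything is generated in code at test time.

make_document <- function(text, id = "D1") {
  frags <- strsplit(text, "[.!?\n]+")[[1]]
  sentences <- lapply(frags, tokenize_words)
  structure(list(patient_id = id, text = text,
                 sentences = sentences[lengths(sentences) > 0]),
            class = "patient_document")
}

make_patient <- function(id, texts, codes = character(0), label = "CONTROL",
                         profile = criterion_profile()) {
  structure(list(patient_id = id,
                 notes = data.frame(note_type = rep("progress", length(texts)),
                                    text = texts, stringsAsFactors = FALSE),
                 icd9_codes = codes, gold_label = label, profile = profile),
            class = "patient_record")
}

small_cohort <- function(n = 60, seed = 7, holdout = 20, ...) {
  generate_cohort(synth_config(n_patients = n, holdout = holdout,
                               seed = seed, ...))
}

# linearly separable toy design: first feature carries the label
separable_matrix <- function(n = 40, p = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c("SLE", "CONTROL"), length.out = n)
  x <- matrix(rnorm(n * p, sd = 0.1), n, p,
              dimnames = list(sprintf("P%02d", seq_len(n)),
                              sprintf("feat%02d", seq_len(p))))
  x[, 1] <- x[, 1] + ifelse(y == "SLE", 2, -2)
  list(x = x, y = y)
}
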
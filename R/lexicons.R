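# Shipped lexicons: ACR criterion phrases, a small synthetic concept
# dictionary standing in for a UMLS subset, a fixed stop-word list, and
# negation cues. All fixed data so runs are reproducible without any
# external terminology licence.

#' ACR classification criteria for SLE
#'
#' The eleven 1997-revision ACR criteria used for SLE classification.
#' A patient classifies as SLE when at least four criteria are met, or —
#' per the SLICC alternative — when biopsy-proven lupus nephritis is present
#' together with ANA or anti-dsDNA antibodies.
#'
#' @return A data.frame with columns `id` (1..11) and `description`.
#' @export
acr_criteria <- function() {
  data.frame(
    id = 1:11,
    description = c(
      "Malar rash", "Discoid rash", "Photosensitivity", "Oral ulcers",
      "Nonerosive arthritis", "Pleuritis or pericarditis", "Renal disorder",
      "Neurologic disorder", "Hematologic disorder", "Immunologic disorder",
      "Positive antinuclear antibody"
    ),
    stringsAsFactors = FALSE
  )
}

#' Criterion phrase lexicon for the synthetic note generator
#'
#' Fixed mapping from each ACR criterion id to a handful of surface phrases
#' the generator can emit (affirmed or negated). Phrases are short clinical
#' collocations; criterion 11 includes the "positive antinuclear antibody"
#' wording and criterion 7 the lupus-nephritis phrase so that downstream
#' concept matching has realistic multiword targets.
#'
#' @return Named list: names are criterion ids `"1"`..`"11"`, values are
#'   character vectors of phrases.
#' @export
criterion_lexicon <- function() {
  list(
    `1`  = c("malar rash", "butterfly rash over the cheeks"),
    `2`  = c("discoid rash", "discoid skin lesions"),
    `3`  = c("photosensitivity", "rash after sun exposure"),
    `4`  = c("oral ulcers", "painless oral ulceration"),
    `5`  = c("nonerosive arthritis", "arthritis of two peripheral joints"),
    `6`  = c("pleuritis", "pericarditis", "pleuritic chest pain"),
    `7`  = c("renal disorder", "persistent proteinuria", "lupus nephritis"),
    `8`  = c("neurologic disorder", "new onset seizures"),
    `9`  = c("hematologic disorder", "thrombocytopenia", "hemolytic anemia"),
    `10` = c("immunologic disorder", "anti dsdna antibody", "positive anti smith antibody"),
    `11` = c("positive antinuclear antibody", "positive ana titer")
  )
}

#' Synthetic concept dictionary
#'
#' A small dictionary mapping synthetic concept unique identifiers (CUIs)
#' to lower-cased surface forms, standing in for a UMLS subset. It
#' deliberately contains the two ambiguity traps observed with real CUI
#' extraction: the abbreviation `"sle"` maps both to systemic lupus
#' erythematosus (C0024141) and to St. Louis Encephalitis (C0014060), and
#' `"er"` maps both to the emergency room visit concept and to Endoplasmic
#' Reticulum (C0014239). An ambiguous form increments every concept it maps
#' to, reproducing the failure mode of dictionary-based concept extraction.
#'
#' @return A `concept_dictionary` object (named list of character vectors;
#'   names are concept ids).
#' @export
default_concept_dictionary <- function() {
  concept_dictionary(list(
    C0024141 = c("systemic lupus erythematosus", "lupus", "sle"),
    C0024143 = c("lupus nephritis"),
    C0014060 = c("st louis encephalitis", "sle"),
    C0003243 = c("antinuclear antibody", "ana"),
    C1704436 = c("emergency room", "er"),
    C0014239 = c("endoplasmic reticulum", "er"),
    C0026764 = c("malar rash", "butterfly rash"),
    C0011603 = c("discoid rash", "discoid skin lesions"),
    C0085635 = c("photosensitivity"),
    C0026639 = c("oral ulcers", "oral ulceration"),
    C0003864 = c("arthritis", "nonerosive arthritis"),
    C0032231 = c("pleuritis", "pleuritic chest pain"),
    C0031046 = c("pericarditis"),
    C0022658 = c("renal disorder", "persistent proteinuria"),
    C0036572 = c("seizures"),
    C0040034 = c("thrombocytopenia"),
    C0002871 = c("hemolytic anemia"),
    C0151332 = c("anti dsdna antibody"),
    C0699177 = c("plaquenil", "hydroxychloroquine")
  ))
}

#' Fixed English stop-word list
#'
#' A fixed, versioned stop-word list for bag-of-words preprocessing.
#' Negators (`not`, `no`, `nor`, and common clinical negation cues) are
#' deliberately NOT stop words, so that "patient does not have lupus"
#' increments both `lupus` and `not` in the term-frequency matrix.
#'
#' @return Character vector of lower-case stop words.
#' @export
stopwords_en <- function() {
  c(
    "a", "about", "above", "after", "again", "all", "am", "an", "and",
    "any", "are", "as", "at", "be", "because", "been", "before", "being",
    "below", "between", "both", "but", "by", "could", "did", "do", "does",
    "doing", "down", "during", "each", "few", "for", "from", "further",
    "had", "has", "have", "having", "he", "her", "here", "hers", "herself",
    "him", "himself", "his", "how", "i", "if", "in", "into", "is", "it",
    "its", "itself", "just", "me", "more", "most", "my", "myself", "of",
    "off", "on", "once", "only", "or", "other", "our", "ours", "ourselves",
    "out", "over", "own", "same", "she", "should", "so", "some", "such",
    "than", "that", "the", "their", "theirs", "them", "themselves", "then",
    "there", "these", "they", "this", "those", "through", "to", "too",
    "under", "until", "up", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with", "you",
    "your", "yours", "yourself", "yourselves"
  )
}

#' Negation cue tokens
#'
#' Cues that flip a concept mention to a negated mention when they occur in
#' the same sentence within the negation window before the mention
#' (NegEx-style trigger terms, single tokens).
#'
#' @return Character vector of lower-case cue tokens.
#' @export
negation_cues <- function() {
  c("no", "not", "denies", "without", "negative", "denied")
}

# Background (class-independent) vocabulary used for noise sentences in the
# synthetic generator. Generic clinical words only.
background_vocabulary <- function() {
  c(
    "patient", "seen", "today", "clinic", "follow", "visit", "review",
    "medication", "dose", "stable", "reports", "exam", "normal", "vitals",
    "blood", "pressure", "heart", "rate", "plan", "continue", "return",
    "weeks", "months", "labs", "ordered", "discussed", "history", "family",
    "tolerating", "well", "mild", "moderate", "noted", "left", "right",
    "knee", "shoulder", "pain", "improved", "unchanged", "assessment"
  )
}

# Sentence templates that embed an ambiguous abbreviation in a context
# unrelated to lupus, mirroring the St. Louis Encephalitis / Endoplasmic
# Reticulum confusions seen with dictionary CUI extraction.
ambiguous_templates <- function() {
  c(
    "patient was seen in the ER last night for chest pain",
    "travel history reviewed given regional SLE arbovirus advisories",
    "ER followup scheduled after discharge",
    "SLE serology panel pending from outside lab"
  )
}
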
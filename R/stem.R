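# Porter2 ("Snowball English") stemmer, implemented from the published
# algorithm definition: marking of consonant y as Y, R1/R2 regions, steps
# 0-5 with longest-suffix ("among") semantics, exceptional word forms, and
# the short-syllable rule. Pure R, memoised over unique tokens.

P2_VOWELS <- c("a", "e", "i", "o", "u", "y")
P2_DOUBLES <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
P2_LI_END <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

p2_is_v <- function(ch) ch %in% P2_VOWELS

p2_ends <- function(w, s) {
  nchar(w) >= nchar(s) && substring(w, nchar(w) - nchar(s) + 1L) == s
}

# start position (1-based) of suffix s in w
p2_suf_start <- function(w, s) nchar(w) - nchar(s) + 1L

p2_repl <- function(w, s, r) {
  paste0(substring(w, 1L, nchar(w) - nchar(s)), r)
}

# R1 start: position after the first non-vowel following a vowel (with the
# gener/commun/arsen prefix exceptions); R2 start: same rule inside R1.
p2_regions <- function(ch) {
  n <- length(ch)
  w <- paste(ch, collapse = "")
  r1 <- n + 1L
  pre <- c("gener", "commun", "arsen")
  hit <- pre[startsWith(w, pre)]
  if (length(hit)) {
    r1 <- nchar(hit[[1L]]) + 1L
  } else if (n >= 2L) {
    for (j in 2:n) {
      if (!p2_is_v(ch[j]) && p2_is_v(ch[j - 1L])) {
        r1 <- j + 1L
        break
      }
    }
  }
  r2 <- n + 1L
  if (r1 + 1L <= n) {
    for (j in (r1 + 1L):n) {
      if (!p2_is_v(ch[j]) && p2_is_v(ch[j - 1L])) {
        r2 <- j + 1L
        break
      }
    }
  }
  c(r1 = r1, r2 = r2)
}

# A short syllable: non-vowel + vowel + non-vowel (not w, x, Y) at the end,
# or vowel + non-vowel comprising the whole two-letter word.
p2_ends_short_syllable <- function(ch) {
  n <- length(ch)
  if (n == 2L) {
    return(p2_is_v(ch[1L]) && !p2_is_v(ch[2L]))
  }
  if (n >= 3L) {
    return(!p2_is_v(ch[n - 2L]) && p2_is_v(ch[n - 1L]) &&
             !p2_is_v(ch[n]) && !(ch[n] %in% c("w", "x", "Y")))
  }
  FALSE
}

p2_is_short <- function(w, r1) {
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  p2_ends_short_syllable(ch) && r1 > length(ch)
}

# longest listed suffix that matches w, or NA
p2_among <- function(w, suffixes) {
  suffixes <- suffixes[order(-nchar(suffixes))]
  for (s in suffixes) if (p2_ends(w, s)) return(s)
  NA_character_
}

p2_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

p2_exceptions2 <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

porter2_stem_word <- function(word) {
  w <- word
  if (nchar(w) <= 2L) return(w)
  if (!is.na(p2_exceptions1[w])) return(unname(p2_exceptions1[w]))
  w <- sub("^'+", "", w)
  if (nchar(w) <= 2L) return(w)

  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  for (i in seq_along(ch)) {
    if (ch[i] == "y" && (i == 1L || p2_is_v(ch[i - 1L]))) ch[i] <- "Y"
  }
  w <- paste(ch, collapse = "")
  reg <- p2_regions(ch)
  r1 <- reg[["r1"]]
  r2 <- reg[["r2"]]

  # step 0: trailing apostrophe forms
  for (s in c("'s'", "'s", "'")) {
    if (p2_ends(w, s)) {
      w <- p2_repl(w, s, "")
      break
    }
  }

  # step 1a
  if (p2_ends(w, "sses")) {
    w <- p2_repl(w, "sses", "ss")
  } else if (p2_ends(w, "ied") || p2_ends(w, "ies")) {
    suf <- if (p2_ends(w, "ied")) "ied" else "ies"
    w <- p2_repl(w, suf, if (nchar(w) > 4L) "i" else "ie")
  } else if (p2_ends(w, "us") || p2_ends(w, "ss")) {
    # leave unchanged
  } else if (p2_ends(w, "s")) {
    n <- nchar(w)
    if (n >= 3L) {
      body <- strsplit(substring(w, 1L, n - 2L), "", fixed = TRUE)[[1L]]
      if (any(p2_is_v(body))) w <- substring(w, 1L, n - 1L)
    }
  }

  if (w %in% p2_exceptions2) return(w)

  # step 1b
  s <- p2_among(w, c("eedly", "ingly", "edly", "eed", "ing", "ed"))
  if (!is.na(s)) {
    if (s %in% c("eed", "eedly")) {
      if (p2_suf_start(w, s) >= r1) w <- p2_repl(w, s, "ee")
    } else {
      pre <- substring(w, 1L, p2_suf_start(w, s) - 1L)
      if (any(p2_is_v(strsplit(pre, "", fixed = TRUE)[[1L]]))) {
        w <- pre
        if (p2_ends(w, "at") || p2_ends(w, "bl") || p2_ends(w, "iz")) {
          w <- paste0(w, "e")
        } else if (nchar(w) >= 2L &&
                   substring(w, nchar(w) - 1L) %in% P2_DOUBLES) {
          w <- substring(w, 1L, nchar(w) - 1L)
        } else if (p2_is_short(w, r1)) {
          w <- paste0(w, "e")
        }
      }
    }
  }

  # step 1c: y/Y -> i after a non-vowel that is not the first letter
  n <- nchar(w)
  if (n >= 3L) {
    last <- substring(w, n, n)
    prev <- substring(w, n - 1L, n - 1L)
    if (last %in% c("y", "Y") && !p2_is_v(prev)) {
      w <- paste0(substring(w, 1L, n - 1L), "i")
    }
  }

  # step 2 (conditions require the suffix to lie in R1)
  step2 <- c(
    ization = "ize", ational = "ate", fulness = "ful", ousness = "ous",
    iveness = "ive", tional = "tion", biliti = "ble", lessli = "less",
    entli = "ent", ation = "ate", alism = "al", aliti = "al",
    ousli = "ous", iviti = "ive", fulli = "ful", enci = "ence",
    anci = "ance", abli = "able", izer = "ize", ator = "ate",
    alli = "al", bli = "ble", ogi = "og", li = ""
  )
  s <- p2_among(w, names(step2))
  if (!is.na(s) && p2_suf_start(w, s) >= r1) {
    ok <- TRUE
    if (s == "ogi") {
      ok <- p2_suf_start(w, s) > 1L &&
        substring(w, p2_suf_start(w, s) - 1L, p2_suf_start(w, s) - 1L) == "l"
    } else if (s == "li") {
      ok <- p2_suf_start(w, s) > 1L &&
        substring(w, p2_suf_start(w, s) - 1L, p2_suf_start(w, s) - 1L) %in% P2_LI_END
    }
    if (ok) w <- p2_repl(w, s, step2[[s]])
  }

  # step 3
  step3 <- c(
    ational = "ate", tional = "tion", alize = "al", icate = "ic",
    iciti = "ic", ative = "", ical = "ic", ness = "", ful = ""
  )
  s <- p2_among(w, names(step3))
  if (!is.na(s) && p2_suf_start(w, s) >= r1) {
    if (s == "ative") {
      if (p2_suf_start(w, s) >= r2) w <- p2_repl(w, s, "")
    } else {
      w <- p2_repl(w, s, step3[[s]])
    }
  }

  # step 4 (suffix must lie in R2)
  step4 <- c(
    "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
    "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic"
  )
  s <- p2_among(w, step4)
  if (!is.na(s) && p2_suf_start(w, s) >= r2) {
    if (s == "ion") {
      prev <- substring(w, p2_suf_start(w, s) - 1L, p2_suf_start(w, s) - 1L)
      if (prev %in% c("s", "t")) w <- p2_repl(w, s, "")
    } else {
      w <- p2_repl(w, s, "")
    }
  }

  # step 5
  n <- nchar(w)
  if (n >= 1L && substring(w, n, n) == "e") {
    if (n >= r2) {
      w <- substring(w, 1L, n - 1L)
    } else if (n >= r1) {
      body <- strsplit(substring(w, 1L, n - 1L), "", fixed = TRUE)[[1L]]
      if (!p2_ends_short_syllable(body)) w <- substring(w, 1L, n - 1L)
    }
  }
  n <- nchar(w)
  if (n >= 2L && substring(w, n, n) == "l" && n >= r2 &&
      substring(w, n - 1L, n - 1L) == "l") {
    w <- substring(w, 1L, n - 1L)
  }

  chartr("Y", "y", w)
}

#' Porter2 (Snowball English) stemming
#'
#' Suffix-stripping normalisation of English word forms with the Porter2
#' algorithm, e.g. `"fatigue" -> "fatigu"`, `"pregnancy" -> "pregnanc"`,
#' `"resolved" -> "resolv"`. Tokens containing any non-alphabetic character
#' (digits, hyphens) are returned unchanged, so numeric tokens survive as
#' features.
#'
#' @param tokens Character vector of lower-case tokens.
#' @return Character vector of stems, same length as `tokens`.
#' @examples
#' porter2_stem(c("fatigue", "pregnancy", "resolved", "912"))
#' @export
porter2_stem <- function(tokens) {
  if (!length(tokens)) return(character(0))
  uniq <- unique(tokens)
  alpha <- grepl("^[a-z']+$", uniq)
  stems <- uniq
  stems[alpha] <- vapply(uniq[alpha], porter2_stem_word, character(1L))
  stems[match(tokens, uniq)]
}

#' Tokenise raw text
#'
#' Case-folds, strips punctuation (every character other than letters,
#' digits and apostrophes becomes a separator) and splits on whitespace.
#'
#' @param text Character scalar or vector; elements are concatenated.
#' @return Character vector of lower-case tokens (possibly empty).
#' @export
tokenize_words <- function(text) {
  text <- tolower(paste(text, collapse = " "))
  text <- gsub("[^a-z0-9']+", " ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  toks[nzchar(toks) & toks != "'"]
}

#' Bag-of-words token preprocessing
#'
#' The bag-of-words preparation chain: punctuation removal and case folding,
#' stop-word removal, then Porter2 stemming. The shipped stop-word list
#' keeps negators (`not`, `no`, ...) so negated mentions remain visible to
#' the term-frequency representation.
#'
#' @param text Character scalar: raw note or document text.
#' @param stopword_list Character vector of stop words; defaults to the
#'   fixed list shipped with the package ([stopwords_en()]).
#' @return Character vector of stems.
#' @examples
#' preprocess_tokens("Fatigue and pregnancy.")
#' @export
preprocess_tokens <- function(text, stopword_list = stopwords_en()) {
  if (!is.character(stopword_list)) {
    stop("`stopword_list` must be a character vector", call. = FALSE)
  }
  toks <- tokenize_words(text)
  toks <- toks[!(toks %in% stopword_list)]
  porter2_stem(toks)
}
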
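# Porter's English suffix-stripping algorithm, implemented from the classic
# definition (measure-based rules over consonant/vowel sequences). Used to
# conflate morphological variants in pathway names ("meiotic"/"meiosis",
# "regulation"/"regulated") before name-similarity scoring.

porter_cv <- function(chars) {
  isv <- logical(length(chars))
  for (i in seq_along(chars)) {
    c <- chars[i]
    isv[i] <- c %in% c("a", "e", "i", "o", "u") ||
      (c == "y" && i > 1L && !isv[i - 1L])
  }
  isv
}

porter_measure <- function(w) {
  if (!nzchar(w)) return(0L)
  p <- paste(ifelse(porter_cv(strsplit(w, "")[[1]]), "V", "C"), collapse = "")
  p <- gsub("C+", "C", gsub("V+", "V", p))
  m <- gregexpr("VC", p, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

porter_has_vowel <- function(w) {
  nzchar(w) && any(porter_cv(strsplit(w, "")[[1]]))
}

porter_double_c <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  a <- substr(w, n - 1, n - 1)
  b <- substr(w, n, n)
  a == b && !porter_cv(strsplit(w, "")[[1]])[n]
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  isv <- porter_cv(strsplit(w, "")[[1]])
  last <- substr(w, n, n)
  !isv[n] && isv[n - 1L] && !isv[n - 2L] && !(last %in% c("w", "x", "y"))
}

porter_stem_word <- function(w) {
  if (nchar(w) <= 2) return(w)
  drop_end <- function(word, k) substr(word, 1, nchar(word) - k)

  # step 1a: plurals
  if (endsWith(w, "sses")) {
    w <- drop_end(w, 2)
  } else if (endsWith(w, "ies")) {
    w <- paste0(drop_end(w, 3), "i")
  } else if (!endsWith(w, "ss") && endsWith(w, "s")) {
    w <- drop_end(w, 1)
  }

  # step 1b: -eed / -ed / -ing
  flag1b <- FALSE
  if (endsWith(w, "eed")) {
    if (porter_measure(drop_end(w, 3)) > 0) w <- drop_end(w, 1)
  } else if (endsWith(w, "ed") && porter_has_vowel(drop_end(w, 2))) {
    w <- drop_end(w, 2)
    flag1b <- TRUE
  } else if (endsWith(w, "ing") && porter_has_vowel(drop_end(w, 3))) {
    w <- drop_end(w, 3)
    flag1b <- TRUE
  }
  if (flag1b) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_c(w) &&
               !endsWith(w, "l") && !endsWith(w, "s") && !endsWith(w, "z")) {
      w <- drop_end(w, 1)
    } else if (porter_measure(w) == 1L && porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: terminal y -> i when a vowel precedes
  if (endsWith(w, "y") && porter_has_vowel(drop_end(w, 1))) {
    w <- paste0(drop_end(w, 1), "i")
  }

  apply_rules <- function(word, rules, cond) {
    for (r in rules) {
      if (endsWith(word, r[[1]])) {
        stem <- substr(word, 1, nchar(word) - nchar(r[[1]]))
        if (cond(stem)) word <- paste0(stem, r[[2]])
        return(word)
      }
    }
    word
  }

  # step 2 (m > 0): double-suffix reduction
  w <- apply_rules(w, list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble")
  ), function(stem) porter_measure(stem) > 0)

  # step 3 (m > 0)
  w <- apply_rules(w, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
    list("ness", "")
  ), function(stem) porter_measure(stem) > 0)

  # step 4 (m > 1): strip residual suffixes; -ion only after s/t
  for (s in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
              "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
              "ous", "ive", "ize")) {
    if (endsWith(w, s)) {
      stem <- substr(w, 1, nchar(w) - nchar(s))
      ok <- porter_measure(stem) > 1 &&
        (s != "ion" || endsWith(stem, "s") || endsWith(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop final e
  if (endsWith(w, "e")) {
    stem <- drop_end(w, 1)
    m <- porter_measure(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) w <- stem
  }
  # step 5b: -ll -> -l when m > 1
  if (porter_measure(w) > 1 && porter_double_c(w) && endsWith(w, "l")) {
    w <- drop_end(w, 1)
  }
  w
}

#' Porter-stem a vector of words
#'
#' @param words Character vector of lower-case words.
#' @return Character vector of stems.
#' @export
#' @examples
#' porter_stem(c("meiosis", "meiotic", "recombination", "signaling"))
porter_stem <- function(words) {
  vapply(tolower(words), porter_stem_word, character(1), USE.NAMES = FALSE)
}

#' Default stopword list for pathway-name tokenization
#'
#' Articles, prepositions and conjunctions only. Domain words such as
#' "pathway" or "signaling" are deliberately kept out of the default list
#' (they carry weak but real signal); pass your own list to override.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "of", "in", "on", "by", "to", "for", "and", "or",
    "with", "via", "from", "into", "through", "as", "at", "its")
}

#' Tokenize a pathway name into a set of stems
#'
#' Lower-cases, splits on non-alphanumeric runs, drops stopwords and
#' single-character tokens, stems the remainder and collapses duplicates.
#'
#' @param name A pathway name (character scalar).
#' @param stopwords Words removed before stemming.
#' @return Character vector (a set) of stems; may be empty.
#' @export
#' @examples
#' tokenize_name("Progesterone-mediated oocyte maturation")
tokenize_name <- function(name, stopwords = default_stopwords()) {
  toks <- strsplit(tolower(name), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks) & nchar(toks) > 1]
  toks <- setdiff(toks, tolower(stopwords))
  unique(porter_stem(toks))
}

#' Name similarity of two pathways
#'
#' Jaccard coefficient of the stemmed token sets of the two names; 0 when
#' either token set is empty (no evidence of similarity).
#'
#' @param a,b Pathway names.
#' @param stopwords Words removed before stemming.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' name_similarity("Oocyte meiosis", "Progesterone-mediated oocyte maturation",
#'                 stopwords = character())
name_similarity <- function(a, b, stopwords = default_stopwords()) {
  ta <- tokenize_name(a, stopwords)
  tb <- tokenize_name(b, stopwords)
  if (length(ta) == 0 || length(tb) == 0) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}
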
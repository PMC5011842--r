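# Porter (1980) suffix-stripping stemmer.
#
# Implemented from the published algorithm definition.  A word is viewed as
# [C](VC)^m[V]; y counts as a vowel when preceded by a consonant.  Conditions
# *v* (stem contains a vowel), *d (ends double consonant) and *o (ends
# consonant-vowel-consonant, final consonant not w, x or y) are evaluated on
# the candidate stem, i.e. the word with the suffix removed.

.vowel_mask <- function(chars) {
  # TRUE where the character acts as a vowel: a,e,i,o,u always; y only when
  # preceded by a consonant (so leading y is a consonant)
  n <- length(chars)
  v <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      v[i] <- TRUE
    } else if (ch == "y") {
      v[i] <- i > 1L && !v[i - 1L]
    }
  }
  v
}

.measure <- function(stem) {
  if (nchar(stem) == 0L) return(0L)
  v <- .vowel_mask(strsplit(stem, "")[[1]])
  # m = number of VC transitions
  r <- rle(v)$values
  sum(r[-length(r)] & !r[-1L])
}

.contains_vowel <- function(stem) {
  nchar(stem) > 0L && any(.vowel_mask(strsplit(stem, "")[[1]]))
}

.ends_double_consonant <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L)
  b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  !.vowel_mask(strsplit(stem, "")[[1]])[n]
}

.ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  v <- .vowel_mask(strsplit(stem, "")[[1]])
  last <- substr(stem, n, n)
  !v[n - 2L] && v[n - 1L] && !v[n] && !(last %in% c("w", "x", "y"))
}

.ends_with <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

.chop <- function(word, suffix) substr(word, 1L, nchar(word) - nchar(suffix))

.porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (.ends_with(word, "sses")) {
    word <- paste0(.chop(word, "sses"), "ss")
  } else if (.ends_with(word, "ies")) {
    word <- paste0(.chop(word, "ies"), "i")
  } else if (.ends_with(word, "ss")) {
    # unchanged
  } else if (.ends_with(word, "s")) {
    word <- .chop(word, "s")
  }

  # Step 1b
  fired <- FALSE
  if (.ends_with(word, "eed")) {
    stem <- .chop(word, "eed")
    if (.measure(stem) > 0L) word <- paste0(stem, "ee")
  } else if (.ends_with(word, "ed") && .contains_vowel(.chop(word, "ed"))) {
    word <- .chop(word, "ed"); fired <- TRUE
  } else if (.ends_with(word, "ing") && .contains_vowel(.chop(word, "ing"))) {
    word <- .chop(word, "ing"); fired <- TRUE
  }
  if (fired) {
    if (.ends_with(word, "at") || .ends_with(word, "bl") ||
        .ends_with(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.ends_double_consonant(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- substr(word, 1L, nchar(word) - 1L)
    } else if (.measure(word) == 1L && .ends_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (.ends_with(word, "y") && .contains_vowel(.chop(word, "y"))) {
    word <- paste0(.chop(word, "y"), "i")
  }

  # Step 2 (condition m(stem) > 0); longest suffix first
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
          ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
          alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
          aliti = "al", iviti = "ive", biliti = "ble")
  s2 <- s2[order(-nchar(names(s2)))]
  for (suf in names(s2)) {
    if (.ends_with(word, suf)) {
      stem <- .chop(word, suf)
      if (.measure(stem) > 0L) word <- paste0(stem, s2[[suf]])
      break
    }
  }

  # Step 3 (condition m(stem) > 0)
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
          ical = "ic", ful = "", ness = "")
  s3 <- s3[order(-nchar(names(s3)))]
  for (suf in names(s3)) {
    if (.ends_with(word, suf)) {
      stem <- .chop(word, suf)
      if (.measure(stem) > 0L) word <- paste0(stem, s3[[suf]])
      break
    }
  }

  # Step 4 (condition m(stem) > 1); "ion" additionally needs stem ending s or t
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
          "ic", "ou")
  s4 <- s4[order(-nchar(s4))]
  for (suf in s4) {
    if (.ends_with(word, suf)) {
      stem <- .chop(word, suf)
      if (suf == "ion" &&
          !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) break
      if (.measure(stem) > 1L) word <- stem
      break
    }
  }

  # Step 5a
  if (.ends_with(word, "e")) {
    stem <- .chop(word, "e")
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) word <- stem
  }

  # Step 5b
  if (.measure(word) > 1L && .ends_double_consonant(word) &&
      substr(word, nchar(word), nchar(word)) == "l") {
    word <- substr(word, 1L, nchar(word) - 1L)
  }

  word
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classical Porter
#' suffix-stripping algorithm, so that inflectional variants such as
#' "connect", "connected", "connecting" and "connection" collapse onto a
#' single feature.  Input is lowercased before stemming; words of one or two
#' characters are returned unchanged.
#'
#' Note that Porter stemming is purely suffix-driven: irregular forms are not
#' conflated (e.g. "took" does not stem to the same string as "take").
#'
#' @param words character vector of words (one word per element).
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("connection", "connected", "connecting"))
#' porter_stem(c("generalizations", "oscillators"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  stopifnot(is.character(words))
  vapply(tolower(words), .porter1, character(1), USE.NAMES = FALSE)
}
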
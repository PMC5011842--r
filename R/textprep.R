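# Deidentification and document-term matrix construction.

.phone_re <- "(\\+?1[-. ]?)?(\\(\\d{3}\\)[-. ]?|\\d{3}[-. ])\\d{3}[-. ]\\d{4}"
.email_re <- "[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}"

#' Scrub person names, phone numbers and email addresses from text
#'
#' Replaces identifying strings with stable numbered placeholders
#' (`person001`, `phone001`, `email001`, ...).  Every occurrence of the same
#' identifier maps to the same placeholder, within and across calls when the
#' previous `replacement_map` is passed back in.
#'
#' Person names are matched as standalone tokens against `person_names`,
#' case-insensitively, but with a capitalization heuristic that resolves
#' name/common-word homographs: a listed name written in lowercase is left
#' alone (it is being used as an ordinary word, as in "the bill"), while a
#' capitalized occurrence is treated as a person and replaced.  Phone numbers
#' and email addresses are recognized by pattern.
#'
#' Scrubbing is idempotent: applying it to already-scrubbed text changes
#' nothing, because placeholders contain digits and never re-match.
#'
#' @param text character vector of raw texts.
#' @param person_names character vector of first and last names to remove
#'   (case-insensitive); may be empty to scrub only phones/emails.
#' @param replacement_map named character vector mapping placeholder ->
#'   original string, from a previous call, to keep numbering stable across
#'   batches.  Default empty.
#' @param prefixes named list with elements `person`, `phone`, `email` giving
#'   the placeholder prefixes.
#' @return an object of class `scrub_result`: list with `scrubbed_text`
#'   (character vector like `text`) and `replacement_map` (named character
#'   vector, placeholder -> original).  Store the map separately from any
#'   shared output.
#' @examples
#' scrub_text("Met with Bill about the bill.", person_names = "Bill")
#' @export
scrub_text <- function(text, person_names = character(0),
                       replacement_map = character(0),
                       prefixes = list(person = "person", phone = "phone",
                                       email = "email")) {
  stopifnot(is.character(text))
  map <- replacement_map

  placeholder_for <- function(original, prefix) {
    nms <- names(map)
    if (is.null(nms)) nms <- character(0)
    hit <- nms[match(tolower(original), tolower(map))]
    if (length(hit) == 1L && !is.na(hit)) return(hit)
    n_used <- sum(startsWith(nms, prefix))
    ph <- sprintf("%s%03d", prefix, n_used + 1L)
    map[ph] <<- original
    ph
  }

  replace_pattern <- function(txt, pattern, prefix) {
    m <- gregexpr(pattern, txt, perl = TRUE)
    regmatches(txt, m) <- lapply(regmatches(txt, m), function(hits) {
      vapply(hits, placeholder_for, character(1), prefix = prefix)
    })
    txt
  }

  out <- vapply(text, function(txt) {
    txt <- replace_pattern(txt, .email_re, prefixes$email)
    txt <- replace_pattern(txt, .phone_re, prefixes$phone)
    if (length(person_names) > 0L) {
      for (nm in person_names) {
        # capitalized occurrences only: "Bill" is a person, "bill" is a word
        cap <- paste0(toupper(substr(nm, 1, 1)), tolower(substr(nm, 2, nchar(nm))))
        pat <- paste0("\\b", cap, "\\b")
        if (grepl(pat, txt)) {
          ph <- placeholder_for(cap, prefixes$person)
          txt <- gsub(pat, ph, txt)
        }
      }
    }
    txt
  }, character(1), USE.NAMES = FALSE)

  structure(list(scrubbed_text = out, replacement_map = map),
            class = "scrub_result")
}

#' @export
print.scrub_result <- function(x, ...) {
  cat("Scrubbed", length(x$scrubbed_text), "text(s);",
      length(x$replacement_map), "identifier(s) replaced\n")
  invisible(x)
}

#' Tokenize and stem a text
#'
#' Splits on non-alphanumeric characters, drops tokens containing digits
#' (numbers and deidentification placeholders such as `person001` are never
#' counted as features), lowercases, and Porter-stems each remaining token.
#'
#' @param text character vector of texts.
#' @return if `text` has length 1, a character vector of stems; otherwise a
#'   list of such vectors.
#' @examples
#' stem_tokens("Connection connected, connecting!")
#' @export
stem_tokens <- function(text) {
  stopifnot(is.character(text))
  one <- function(txt) {
    toks <- strsplit(txt, "[^[:alnum:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!grepl("[0-9]", toks)]
    if (length(toks) == 0L) return(character(0))
    porter_stem(toks)
  }
  res <- lapply(text, one)
  if (length(text) == 1L) res[[1]] else res
}

#' Build the row-normalized document x keyword matrix
#'
#' Counts occurrences of each keyword stem in each stemmed document and
#' divides each row by the document's total keyword count, so that every row
#' with at least one keyword hit sums to exactly 1.  Documents containing no
#' keyword become all-zero rows and are reported in `zero_rows` (optionally
#' imputed as uniform rows instead).
#'
#' @param documents character vector of document texts (raw; stemming is done
#'   internally) or a list of pre-stemmed token vectors.
#' @param keywords ordered character vector of keyword stems (the feature
#'   list W).
#' @param impute_uniform if TRUE, zero-keyword documents get a uniform row
#'   `1/K` instead of zeros; they are still listed in `zero_rows`.
#' @return an object of class `doc_term_matrix`: list with `X` (L x K
#'   matrix), `keywords`, `doc_index` (row -> document position), and
#'   `zero_rows` (integer indices).
#' @export
build_doc_term_matrix <- function(documents, keywords,
                                  impute_uniform = FALSE) {
  stopifnot(length(keywords) > 0L, !anyDuplicated(keywords))
  stems <- if (is.list(documents)) documents else
    lapply(documents, function(d) stem_tokens(d))
  L <- length(stems)
  K <- length(keywords)
  X <- matrix(0, L, K, dimnames = list(NULL, keywords))
  for (i in seq_len(L)) {
    hit <- factor(stems[[i]], levels = keywords)
    cnt <- tabulate(hit, nbins = K)
    X[i, ] <- cnt
  }
  tot <- rowSums(X)
  zero_rows <- which(tot == 0)
  nz <- tot > 0
  X[nz, ] <- X[nz, , drop = FALSE] / tot[nz]
  if (impute_uniform && length(zero_rows) > 0L) {
    X[zero_rows, ] <- 1 / K
  }
  structure(list(X = X, keywords = keywords, doc_index = seq_len(L),
                 zero_rows = zero_rows),
            class = "doc_term_matrix")
}

#' @export
print.doc_term_matrix <- function(x, ...) {
  cat("Document-term matrix:", nrow(x$X), "documents x",
      length(x$keywords), "keywords;",
      length(x$zero_rows), "zero row(s)\n")
  invisible(x)
}

#' Read a plain-text name list (one name per line)
#'
#' @param path file path; blank lines and leading/trailing whitespace are
#'   dropped.
#' @return character vector of names.
#' @export
read_name_list <- function(path) {
  stopifnot(file.exists(path))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a scrub replacement map as delimited text
#'
#' The map re-identifies individuals, so write it to an access-restricted
#' location, never next to shared outputs.
#'
#' @param scrub a `scrub_result`.
#' @param path output CSV path (columns `placeholder`, `original`).
#' @export
write_scrub_map <- function(scrub, path) {
  stopifnot(inherits(scrub, "scrub_result"))
  utils::write.csv(
    data.frame(placeholder = names(scrub$replacement_map),
               original = unname(scrub$replacement_map),
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}
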
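# Max-relevance / min-redundancy keyword selection from stage descriptions.
#
# For stage i with description documents A_i (m sentences), relevance of a
# candidate stem w is the cosine between its per-document occurrence-count
# vector and the per-document total word-count vector; redundancy against an
# already-selected stem is the cosine of their per-document count vectors.
# Keywords are chosen greedily: the k-th pick maximizes
#   relevance(w) - (1/(k-1)) * sum over selected of cosine(w, selected)
# with the redundancy term defined as 0 at k = 1, ties broken by
# lexicographic stem order.

#' Cosine similarity of two non-negative vectors
#'
#' @param u,v numeric vectors of equal length, each with at least one
#'   non-zero entry.
#' @return the cosine (dot product over the product of Euclidean norms), in
#'   `[0, 1]` for non-negative input.
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Per-stage vocabulary with per-document stem counts
#'
#' Stems every description sentence of one stage and records, for each unique
#' stem, how often it occurs in each sentence, together with each sentence's
#' total stem count.
#'
#' @param sentences character vector: the description sentences of one stage.
#' @param stage_id integer stage identifier carried along for provenance.
#' @return object of class `stage_vocabulary`: list with `stage_id`, `stems`
#'   (sorted unique stems P_i), `counts` (|P_i| x m matrix of per-document
#'   occurrence counts), `doc_totals` (length-m total stem counts).
#' @export
stage_vocabulary <- function(sentences, stage_id = NA_integer_) {
  stopifnot(is.character(sentences), length(sentences) >= 1)
  toks <- lapply(sentences, function(s) stem_tokens(s))
  stems <- sort(unique(unlist(toks)))
  if (length(stems) == 0L) stop("stage ", stage_id, " has no stemmable words")
  m <- length(sentences)
  counts <- matrix(0L, length(stems), m,
                   dimnames = list(stems, NULL))
  for (j in seq_len(m)) {
    tb <- table(factor(toks[[j]], levels = stems))
    counts[, j] <- as.integer(tb)
  }
  structure(list(stage_id = as.integer(stage_id), stems = stems,
                 counts = counts,
                 doc_totals = vapply(toks, length, integer(1))),
            class = "stage_vocabulary")
}

#' @export
print.stage_vocabulary <- function(x, ...) {
  cat("Stage", x$stage_id, "vocabulary:", length(x$stems), "unique stems in",
      ncol(x$counts), "description sentence(s)\n")
  invisible(x)
}

#' Relevance of a keyword to a stage
#'
#' Cosine between the m-vector of the stem's per-sentence occurrence counts
#' and the m-vector of per-sentence total word counts.  A stem absent from
#' every sentence has relevance 0 by convention.
#'
#' @param w a stem.
#' @param vocab a [stage_vocabulary()].
#' @return relevance in `[0, 1]`.
#' @export
stage_relevance <- function(w, vocab) {
  stopifnot(inherits(vocab, "stage_vocabulary"))
  if (!w %in% vocab$stems) return(0)
  cosine_similarity(vocab$counts[w, ], vocab$doc_totals)
}

#' Greedy max-relevance / min-redundancy keyword selection for one stage
#'
#' @param vocab a [stage_vocabulary()].
#' @param n_keywords number of stems to select (>= 1); selection stops early
#'   if the vocabulary is exhausted.
#' @return character vector of selected stems, in selection order.
#' @export
mrmr_select <- function(vocab, n_keywords) {
  stopifnot(inherits(vocab, "stage_vocabulary"))
  if (n_keywords < 1) stop("n_keywords must be >= 1")
  stems <- vocab$stems                      # sorted: lexicographic tie break
  rel <- vapply(stems, stage_relevance, numeric(1), vocab = vocab)
  selected <- character(0)
  red_sum <- setNames(numeric(length(stems)), stems)
  remaining <- stems
  while (length(selected) < n_keywords && length(remaining) > 0L) {
    k <- length(selected) + 1L
    score <- rel[remaining] -
      if (k == 1L) 0 else red_sum[remaining] / (k - 1L)
    pick <- remaining[which.max(score)]     # first max = lexicographic tie break
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(w)
          cosine_similarity(vocab$counts[w, ], vocab$counts[pick, ]),
          numeric(1))
    }
  }
  selected
}

#' Select keywords for every stage and derive keyword stage labels
#'
#' Runs [mrmr_select()] per stage and merges the selections into one ordered
#' keyword list (stage-major, selection order, duplicates kept once at first
#' appearance).  A keyword selected by exactly one stage is "uniquely
#' occurring" and carries that stage as its label; keywords selected by
#' several stages stay unlabeled.
#'
#' @param descriptions a [stage_descriptions()].
#' @param n_keywords total keyword budget K.
#' @param budget `"split"` divides K evenly across stages (remainder to the
#'   earliest stages); `"per_stage"` selects `n_keywords` from every stage.
#' @return object of class `keyword_set`: list with `keywords` (ordered
#'   character vector W), `provenance` (named list: keyword -> integer vector
#'   of selecting stages), `unique_stage` (named integer vector, `NA` where
#'   multi-stage), and `selections` (per-stage lists).
#' @export
select_keywords <- function(descriptions, n_keywords = 20,
                            budget = c("split", "per_stage")) {
  stopifnot(inherits(descriptions, "stage_descriptions"))
  budget <- match.arg(budget)
  S <- descriptions$n_stages
  per_stage <- if (budget == "split") {
    base <- n_keywords %/% S
    extra <- n_keywords %% S
    base + as.integer(seq_len(S) <= extra)
  } else rep(as.integer(n_keywords), S)
  if (any(per_stage < 1))
    stop("keyword budget ", n_keywords, " leaves a stage with no keywords; ",
         "increase n_keywords or use budget = \"per_stage\"")
  selections <- lapply(seq_len(S), function(s) {
    vocab <- stage_vocabulary(descriptions$sentences[[s]], stage_id = s)
    mrmr_select(vocab, per_stage[s])
  })
  build_keyword_labels(selections)
}

#' Merge per-stage selections into a labeled keyword set
#'
#' @param selections list of length S; element s is the ordered keyword list
#'   selected for stage s.
#' @return a `keyword_set` (see [select_keywords()]).
#' @export
build_keyword_labels <- function(selections) {
  stopifnot(is.list(selections), length(selections) >= 1,
            all(vapply(selections, length, integer(1)) > 0L))
  W <- character(0)
  prov <- list()
  for (s in seq_along(selections)) {
    for (w in selections[[s]]) {
      if (is.null(prov[[w]])) {
        W <- c(W, w)
        prov[[w]] <- s
      } else {
        prov[[w]] <- c(prov[[w]], s)
      }
    }
  }
  unique_stage <- vapply(W, function(w) {
    if (length(prov[[w]]) == 1L) prov[[w]] else NA_integer_
  }, integer(1))
  structure(list(keywords = W, provenance = prov[W],
                 unique_stage = unique_stage, selections = selections),
            class = "keyword_set")
}

#' @export
print.keyword_set <- function(x, ...) {
  cat("Keyword set:", length(x$keywords), "keywords;",
      sum(!is.na(x$unique_stage)), "uniquely staged (labeled)\n")
  invisible(x)
}

#' Write a keyword set as delimited text
#' @param kw a `keyword_set`.
#' @param path output CSV (`keyword,stage_provenance,unique_stage`); multiple
#'   provenance stages are separated by `;`.
#' @export
write_keyword_set <- function(kw, path) {
  stopifnot(inherits(kw, "keyword_set"))
  df <- data.frame(
    keyword = kw$keywords,
    stage_provenance = vapply(kw$provenance, paste, character(1),
                              collapse = ";"),
    unique_stage = ifelse(is.na(kw$unique_stage), "",
                          as.character(kw$unique_stage)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a keyword set written by [write_keyword_set()]
#' @param path CSV path.
#' @return a `keyword_set` (without per-stage `selections`).
#' @export
read_keyword_set <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  prov <- lapply(strsplit(df$stage_provenance, ";", fixed = TRUE), as.integer)
  names(prov) <- df$keyword
  unique_stage <- vapply(df$unique_stage, function(u)
    if (nzchar(u)) as.integer(u) else NA_integer_, integer(1))
  names(unique_stage) <- df$keyword
  structure(list(keywords = df$keyword, provenance = prov,
                 unique_stage = unique_stage, selections = NULL),
            class = "keyword_set")
}
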
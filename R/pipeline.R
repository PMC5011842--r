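# End-to-end pipeline: descriptions -> keywords -> document-term matrix ->
# semi-supervised factorization -> per-note stage probabilities.

#' Run the full stage-classification pipeline
#'
#' Selects keywords from the stage descriptions, builds the row-normalized
#' note x keyword matrix, assembles the partial-label constraints (labeled
#' notes from the corpus; keyword labels from uniquely-staged keywords;
#' optionally the description sentences themselves appended as fully labeled
#' pseudo-notes), fits the semi-supervised factorization, and classifies
#' every note.
#'
#' @param corpus a `log_corpus`.
#' @param descriptions a `stage_descriptions` with the same number of
#'   stages.
#' @param n_keywords total keyword budget K (default 20).
#' @param budget keyword budget scheme, see [select_keywords()].
#' @param include_descriptions if TRUE (default), each description sentence
#'   is appended to the document set as a note labeled with its stage, so
#'   the descriptions act as labeled training documents.
#' @param alpha,beta supervision weights (default 1).
#' @param tol,max_iter,update_rule,seed passed to [fit_semi_nmf()].
#' @param collapse_at category pooling for the output calls (`NULL`: none).
#' @return list with `keywords` (`keyword_set`), `dtm` (`doc_term_matrix`
#'   over notes plus any appended descriptions), `constraints`, `fit`
#'   (`seminmf_fit`), and `assignments` (`stage_assignments`, notes only).
#' @export
run_stage_pipeline <- function(corpus, descriptions, n_keywords = 20,
                               budget = "split",
                               include_descriptions = TRUE,
                               alpha = 1, beta = 1,
                               tol = 1e-6, max_iter = 500,
                               update_rule = "gradient",
                               seed = 1L, collapse_at = NULL) {
  stopifnot(inherits(corpus, "log_corpus"),
            inherits(descriptions, "stage_descriptions"))
  if (corpus$n_stages != descriptions$n_stages)
    stop("corpus has ", corpus$n_stages, " stages but descriptions have ",
         descriptions$n_stages)
  S <- corpus$n_stages

  kw <- select_keywords(descriptions, n_keywords = n_keywords,
                        budget = budget)

  docs <- corpus$notes$text
  note_labels <- corpus$notes$label
  if (include_descriptions) {
    desc_sentences <- unlist(descriptions$sentences, use.names = FALSE)
    desc_labels <- rep(seq_len(S),
                       vapply(descriptions$sentences, length, integer(1)))
    docs <- c(docs, desc_sentences)
    note_labels <- c(note_labels, desc_labels)
  }
  dtm <- build_doc_term_matrix(docs, kw$keywords)
  constraints <- label_constraints(note_labels, kw$unique_stage, S,
                                   alpha = alpha, beta = beta)
  fit <- fit_semi_nmf(dtm$X, constraints, max_iter = max_iter, tol = tol,
                      seed = seed, update_rule = update_rule)
  assignments <- classify_notes(fit, corpus, collapse_at = collapse_at)
  list(keywords = kw, dtm = dtm, constraints = constraints, fit = fit,
       assignments = assignments)
}
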
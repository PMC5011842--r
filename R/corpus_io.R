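# Reading and writing log-note corpora, stage descriptions and
# stage-assignment outputs.
#
# A corpus file is delimited text (CSV, header site_id,date,text,label) or
# line-delimited JSON records with the same fields; label is an integer stage
# in 1..S or empty/missing for unlabeled notes.  Dates are ISO 8601 calendar
# dates.  Within a site, notes are kept in non-decreasing date order; equal
# dates preserve input order (real logs contain same-day notes, so ties are
# allowed and broken stably).

#' Construct a log-note corpus
#'
#' @param notes data.frame with columns `site_id` (character), `date`
#'   (`Date` or ISO 8601 string), `text` (character), `label` (integer stage
#'   in `1..n_stages` or `NA` for unlabeled).
#' @param n_stages number of stages S (>= 2).
#' @return object of class `log_corpus`: list with `notes` (per-site
#'   date-sorted data.frame), `sites`, `n_stages`.
#' @export
log_corpus <- function(notes, n_stages) {
  stopifnot(is.data.frame(notes), n_stages >= 2)
  required <- c("site_id", "date", "text")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols) > 0L)
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"label" %in% names(notes)) notes$label <- NA_integer_
  notes$site_id <- as.character(notes$site_id)
  notes$date <- as.Date(notes$date)
  if (anyNA(notes$date)) stop("unparseable date in corpus")
  notes$text <- as.character(notes$text)
  if (any(!nzchar(trimws(notes$text))))
    stop("empty text in corpus; drop such records before construction")
  notes$label <- as.integer(notes$label)
  bad <- !is.na(notes$label) & (notes$label < 1L | notes$label > n_stages)
  if (any(bad))
    stop("label out of range 1..", n_stages, " in record(s) ",
         paste(which(bad), collapse = ", "))
  # stable per-site date sort; ties keep input order
  ord <- order(notes$site_id, notes$date, seq_len(nrow(notes)), method = "radix")
  notes <- notes[ord, , drop = FALSE]
  rownames(notes) <- NULL
  structure(list(notes = notes, sites = unique(notes$site_id),
                 n_stages = as.integer(n_stages)),
            class = "log_corpus")
}

#' @export
print.log_corpus <- function(x, ...) {
  n_lab <- sum(!is.na(x$notes$label))
  cat("Log-note corpus:", nrow(x$notes), "notes from", length(x$sites),
      "sites;", x$n_stages, "stages;", n_lab, "labeled\n")
  invisible(x)
}

#' Read a log-note corpus from disk
#'
#' Accepts delimited text with header `site_id,date,text,label` or
#' line-delimited JSON (one record per line, same fields; detected from the
#' first non-empty character being `{`).  An empty `label` means unlabeled.
#'
#' Records with empty text are dropped with a warning giving their count;
#' unparseable dates and out-of-range labels are record-level errors that
#' name the offending line.
#'
#' @param path input file path.
#' @param n_stages number of stages S.
#' @return a [log_corpus()].
#' @export
read_log_notes <- function(path, n_stages) {
  stopifnot(file.exists(path))
  first <- ""
  con <- file(path, "r"); on.exit(close(con))
  while (!nzchar(first)) {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("empty corpus file: ", path)
    first <- trimws(ln)
  }
  if (startsWith(first, "{")) {
    lines <- c(first, readLines(con, warn = FALSE))
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(
      site_id = vapply(recs, function(r) as.character(r$site_id), character(1)),
      date = vapply(recs, function(r) as.character(r$date), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      label = vapply(recs, function(r) {
        if (is.null(r$label) || identical(r$label, "")) NA_integer_
        else as.integer(r$label)
      }, integer(1)),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    if (!"label" %in% names(df)) df$label <- ""
    df$label <- ifelse(nzchar(trimws(df$label)), df$label, NA)
  }
  line_no <- seq_len(nrow(df)) + if (startsWith(first, "{")) 0L else 1L
  parsed <- as.Date(df$date, optional = TRUE)
  if (anyNA(parsed))
    stop("unparseable date at line(s) ",
         paste(line_no[is.na(parsed)], collapse = ", "), " of ", path)
  lab <- suppressWarnings(as.integer(df$label))
  bad <- !is.na(df$label) & (is.na(lab) | lab < 1L | lab > n_stages)
  if (any(bad))
    stop("invalid label (must be 1..", n_stages, ") at line(s) ",
         paste(line_no[bad], collapse = ", "), " of ", path)
  empty <- !nzchar(trimws(df$text))
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty text dropped")
    df <- df[!empty, , drop = FALSE]
    parsed <- parsed[!empty]; lab <- lab[!empty]
  }
  log_corpus(data.frame(site_id = df$site_id, date = parsed, text = df$text,
                        label = lab, stringsAsFactors = FALSE),
             n_stages = n_stages)
}

#' Write a log-note corpus as CSV
#'
#' Inverse of [read_log_notes()]: round-tripping preserves site, date, text
#' and label exactly.
#'
#' @param corpus a `log_corpus`.
#' @param path output path.
#' @export
write_log_notes <- function(corpus, path) {
  stopifnot(inherits(corpus, "log_corpus"))
  df <- corpus$notes
  df$date <- format(df$date, "%Y-%m-%d")
  df$label <- ifelse(is.na(df$label), "", as.character(df$label))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct stage descriptions
#'
#' @param sentences list of length S; element i is a character vector of the
#'   description sentences for stage i.
#' @return object of class `stage_descriptions`.
#' @export
stage_descriptions <- function(sentences) {
  stopifnot(is.list(sentences), length(sentences) >= 2)
  n_sent <- vapply(sentences, length, integer(1))
  empty <- which(n_sent == 0L |
                   vapply(sentences, function(s) all(!nzchar(trimws(s))),
                          logical(1)))
  if (length(empty) > 0L)
    stop("stage ", paste(empty, collapse = ", "), " has no descriptions")
  structure(list(sentences = lapply(sentences, as.character),
                 n_stages = length(sentences)),
            class = "stage_descriptions")
}

#' @export
print.stage_descriptions <- function(x, ...) {
  cat("Stage descriptions:", x$n_stages, "stages,",
      sum(vapply(x$sentences, length, integer(1))), "sentences\n")
  invisible(x)
}

#' Read stage descriptions from delimited text
#'
#' Expected header `stage_id,sentence`, one description sentence per row.
#' Every stage in `1..n_stages` must have at least one sentence.
#'
#' @param path input CSV path.
#' @param n_stages number of stages S.
#' @return a [stage_descriptions()].
#' @export
read_stage_descriptions <- function(path, n_stages) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("stage_id", "sentence") %in% names(df)))
  sid <- as.integer(df$stage_id)
  if (anyNA(sid) || any(sid < 1L | sid > n_stages))
    stop("stage_id outside 1..", n_stages, " in ", path)
  sentences <- lapply(seq_len(n_stages), function(s) df$sentence[sid == s])
  missing_stage <- which(vapply(sentences, length, integer(1)) == 0L)
  if (length(missing_stage) > 0L)
    stop("stage ", paste(missing_stage, collapse = ", "),
         " has no descriptions")
  stage_descriptions(sentences)
}

#' Write stage descriptions as delimited text
#' @param descriptions a `stage_descriptions`.
#' @param path output CSV path (`stage_id,sentence`).
#' @export
write_stage_descriptions <- function(descriptions, path) {
  stopifnot(inherits(descriptions, "stage_descriptions"))
  df <- do.call(rbind, lapply(seq_len(descriptions$n_stages), function(s) {
    data.frame(stage_id = s, sentence = descriptions$sentences[[s]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Collapse a stage id into a category id
#'
#' Stages at or above `collapse_at` pool into the last category, mirroring
#' experiments that use categories 1, 2, 3 and "4 or above".
#'
#' @param stage integer vector of stage ids.
#' @param collapse_at pooling threshold in `2..S`, or `NULL` for no pooling.
#' @return integer vector of category ids.
#' @export
collapse_stage <- function(stage, collapse_at = NULL) {
  if (is.null(collapse_at)) return(as.integer(stage))
  as.integer(pmin(as.integer(stage), as.integer(collapse_at)))
}

#' Tabulate labeled and unlabeled notes per stage category
#'
#' @param corpus a `log_corpus`.
#' @param collapse_at pooling threshold (see [collapse_stage()]); default 4,
#'   the four-category scheme (stages 1, 2, 3, 4-or-above).  `NULL` keeps all
#'   S stages separate.
#' @return object of class `count_summary`: list with `labeled` and
#'   `unlabeled` per-category counts, `categories`, and totals.  Unlabeled
#'   notes have no stage, so `unlabeled` is a single total unless the corpus
#'   carries a `true_stage` column (as synthetic corpora do), in which case
#'   both rows are tabulated by the true stage.
#' @export
summarize_counts <- function(corpus, collapse_at = 4) {
  stopifnot(inherits(corpus, "log_corpus"))
  if (!is.null(collapse_at))
    stopifnot(collapse_at >= 2, collapse_at <= corpus$n_stages)
  n_cat <- if (is.null(collapse_at)) corpus$n_stages else as.integer(collapse_at)
  notes <- corpus$notes
  is_lab <- !is.na(notes$label)
  stage_of <- function(idx) {
    s <- notes$label[idx]
    if ("true_stage" %in% names(notes)) {
      s[is.na(s)] <- notes$true_stage[idx][is.na(s)]
    }
    s
  }
  tab <- function(idx) {
    s <- collapse_stage(stage_of(idx), collapse_at)
    cnt <- tabulate(s[!is.na(s)], nbins = n_cat)
    names(cnt) <- category_names(n_cat, collapse_at)
    cnt
  }
  labeled <- tab(which(is_lab))
  unlabeled <- tab(which(!is_lab))
  n_unknown <- sum(!is_lab) - sum(unlabeled)  # unlabeled notes of unknown stage
  structure(list(labeled = labeled, unlabeled = unlabeled,
                 unlabeled_unknown_stage = n_unknown,
                 total_labeled = sum(is_lab), total_unlabeled = sum(!is_lab),
                 total = nrow(notes)),
            class = "count_summary")
}

category_names <- function(n_cat, collapse_at) {
  nm <- as.character(seq_len(n_cat))
  if (!is.null(collapse_at)) nm[n_cat] <- paste0(n_cat, "+")
  nm
}

#' @export
print.count_summary <- function(x, ...) {
  m <- rbind(labeled = x$labeled, unlabeled = x$unlabeled)
  print(m)
  if (x$unlabeled_unknown_stage > 0)
    cat("(plus", x$unlabeled_unknown_stage,
        "unlabeled notes of unknown stage)\n")
  cat("Totals: labeled", x$total_labeled, "| unlabeled", x$total_unlabeled,
      "| all", x$total, "\n")
  invisible(x)
}

#' Write per-note stage assignments
#'
#' One output row per note, in corpus order: `site_id`, `date`,
#' `predicted_category` (argmax with lowest-index tie break), then one
#' probability column per category.
#'
#' @param corpus a `log_corpus`.
#' @param probabilities numeric matrix, one row per note, one column per
#'   category; rows should sum to 1.
#' @param path output CSV path.
#' @param digits rounding precision for probabilities (default 6).
#' @return the path, invisibly.
#' @export
write_stage_assignments <- function(corpus, probabilities, path, digits = 6) {
  stopifnot(inherits(corpus, "log_corpus"))
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != nrow(corpus$notes))
    stop("probability rows (", nrow(probabilities),
         ") do not match corpus size (", nrow(corpus$notes), ")")
  pred <- max.col(probabilities, ties.method = "first")
  p <- round(probabilities, digits)
  colnames(p) <- paste0("p_", seq_len(ncol(p)))
  df <- data.frame(site_id = corpus$notes$site_id,
                   date = format(corpus$notes$date, "%Y-%m-%d"),
                   predicted_category = pred,
                   p, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read stage assignments written by [write_stage_assignments()]
#' @param path CSV path.
#' @return data.frame with `site_id`, `date` (Date), `predicted_category`,
#'   and probability columns `p_1..p_C`.
#' @export
read_stage_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
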
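# From factorization probabilities to stage calls, evaluation metrics,
# per-site stage intervals, attainment flags and Markov transition matrices.

#' Per-note stage-category probabilities and calls
#'
#' Aligns the F rows of a fit with the corpus notes, optionally pools stages
#' at or above `collapse_at` into one category by summing their
#' probabilities, and takes the argmax category (lowest index on ties).
#'
#' @param fit a `seminmf_fit` whose first `nrow(corpus$notes)` F rows
#'   correspond to the corpus notes in order (rows beyond that, e.g. appended
#'   description sentences, are ignored).
#' @param corpus a `log_corpus`.
#' @param collapse_at pooling threshold (see [collapse_stage()]); `NULL`
#'   keeps all stages.
#' @return object of class `stage_assignments`: data.frame with `site_id`,
#'   `date`, `category`, and probability columns `p_1..p_C`; the probability
#'   matrix is also attached as attribute `"prob"`.
#' @export
classify_notes <- function(fit, corpus, collapse_at = NULL) {
  stopifnot(inherits(fit, "seminmf_fit"), inherits(corpus, "log_corpus"))
  L <- nrow(corpus$notes)
  if (nrow(fit$F) < L)
    stop("fit has ", nrow(fit$F), " note rows but corpus has ", L)
  P <- fit$F[seq_len(L), , drop = FALSE]
  P <- collapse_probabilities(P, collapse_at)
  cat_hat <- max.col(P, ties.method = "first")
  colnames(P) <- paste0("p_", seq_len(ncol(P)))
  out <- data.frame(site_id = corpus$notes$site_id,
                    date = corpus$notes$date,
                    category = cat_hat,
                    P, stringsAsFactors = FALSE)
  attr(out, "prob") <- P
  class(out) <- c("stage_assignments", "data.frame")
  out
}

#' Pool stage-probability columns into categories
#'
#' @param P L x S probability matrix.
#' @param collapse_at pooling threshold or `NULL`.
#' @return L x C matrix; columns at or above `collapse_at` are summed.
#' @export
collapse_probabilities <- function(P, collapse_at = NULL) {
  P <- as.matrix(P)
  if (is.null(collapse_at) || collapse_at >= ncol(P)) return(P)
  stopifnot(collapse_at >= 2)
  keep <- P[, seq_len(collapse_at - 1L), drop = FALSE]
  pooled <- rowSums(P[, collapse_at:ncol(P), drop = FALSE])
  cbind(keep, pooled, deparse.level = 0)
}

#' Accuracy and confusion matrix of categorical predictions
#'
#' @param predicted,truth integer category vectors of equal positive length.
#' @param n_categories number of categories C; default the largest category
#'   seen.
#' @return object of class `evaluation_report`: list with `accuracy`,
#'   `confusion` (C x C counts, rows = true, columns = predicted), `n`.
#' @export
evaluate_predictions <- function(predicted, truth, n_categories = NULL) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  n <- length(truth)
  if (n == 0L) stop("no predictions to evaluate")
  if (anyNA(predicted) || anyNA(truth)) stop("NA category")
  C <- if (is.null(n_categories)) max(predicted, truth) else
    as.integer(n_categories)
  confusion <- matrix(0L, C, C, dimnames = list(true = seq_len(C),
                                                predicted = seq_len(C)))
  for (i in seq_len(n))
    confusion[truth[i], predicted[i]] <- confusion[truth[i], predicted[i]] + 1L
  structure(list(accuracy = sum(diag(confusion)) / n,
                 confusion = confusion, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Accuracy:", sprintf("%.1f%%", 100 * x$accuracy), "on", x$n,
      "notes\nConfusion (rows = true, columns = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Detect sustained high-probability runs as stage intervals
#'
#' A stage interval opens at the first date of a run of at least `min_run`
#' consecutive notes whose stage probability is at or above `threshold`, and
#' closes at the last date of that run.  Disjoint runs yield multiple
#' intervals (stage re-entry).  An optional centered moving average smooths
#' the probability series first.
#'
#' @param dates `Date` vector, non-decreasing.
#' @param prob numeric vector of stage probabilities, same length.
#' @param threshold probability threshold in (0, 1); default 0.5.
#' @param min_run minimum run length (>= 1); default 2.
#' @param smooth_window odd moving-average window; `NULL` (default) disables
#'   smoothing.
#' @return data.frame with columns `start`, `end` (dates), `start_idx`,
#'   `end_idx` (note positions); zero rows if no qualifying run.
#' @export
detect_stage_interval <- function(dates, prob, threshold = 0.5, min_run = 2,
                                  smooth_window = NULL) {
  stopifnot(length(dates) == length(prob), threshold > 0, threshold < 1,
            min_run >= 1)
  if (is.unsorted(dates)) stop("dates must be non-decreasing")
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
    prob <- stats::filter(prob, rep(1 / smooth_window, smooth_window),
                          sides = 2)
    # shrink the window at the edges instead of dropping them
    n <- length(prob); h <- (smooth_window - 1) / 2
    for (i in which(is.na(prob))) {
      lo <- max(1, i - h); hi <- min(n, i + h)
      prob[i] <- mean(prob[lo:hi], na.rm = TRUE)
    }
    prob <- as.numeric(prob)
  }
  above <- prob >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = dates[starts[keep]], end = dates[ends[keep]],
             start_idx = starts[keep], end_idx = ends[keep])
}

#' Per-site stage trajectories with detected intervals
#'
#' @param assignments a `stage_assignments` (from [classify_notes()]).
#' @param threshold,min_run,smooth_window see [detect_stage_interval()].
#' @return object of class `stage_trajectories`: named list (one element per
#'   site) with `site_id`, `dates`, `prob` (note x category), `category`,
#'   and `intervals` (data.frame `stage`, `start`, `end`, `start_idx`,
#'   `end_idx`).
#' @export
site_trajectories <- function(assignments, threshold = 0.5, min_run = 2,
                              smooth_window = NULL) {
  stopifnot(inherits(assignments, "stage_assignments"))
  P <- attr(assignments, "prob")
  sites <- unique(assignments$site_id)
  out <- lapply(sites, function(s) {
    idx <- which(assignments$site_id == s)
    Ps <- P[idx, , drop = FALSE]
    iv <- do.call(rbind, lapply(seq_len(ncol(Ps)), function(stage) {
      d <- detect_stage_interval(assignments$date[idx], Ps[, stage],
                                 threshold, min_run, smooth_window)
      if (nrow(d) == 0L) return(NULL)
      cbind(stage = stage, d)
    }))
    if (is.null(iv))
      iv <- data.frame(stage = integer(0), start = as.Date(character(0)),
                       end = as.Date(character(0)), start_idx = integer(0),
                       end_idx = integer(0))
    list(site_id = s, dates = assignments$date[idx], prob = Ps,
         category = assignments$category[idx], intervals = iv)
  })
  names(out) <- sites
  structure(out, class = "stage_trajectories")
}

#' @export
print.stage_trajectories <- function(x, ...) {
  n_iv <- sum(vapply(x, function(s) nrow(s$intervals), integer(1)))
  cat("Stage trajectories for", length(x), "sites;", n_iv,
      "detected intervals\n")
  invisible(x)
}

#' Write detected intervals as delimited text
#' @param trajectories a `stage_trajectories`.
#' @param path output CSV (`site_id,stage,start,end`).
#' @export
write_intervals <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "stage_trajectories"))
  df <- do.call(rbind, lapply(trajectories, function(s) {
    if (nrow(s$intervals) == 0L) return(NULL)
    data.frame(site_id = s$site_id, stage = s$intervals$stage,
               start = format(s$intervals$start, "%Y-%m-%d"),
               end = format(s$intervals$end, "%Y-%m-%d"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(site_id = character(0), stage = integer(0),
                     start = character(0), end = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Flag sites that appear to have attained a stage
#'
#' A site is flagged when any of its notes is predicted at or above `stage`.
#' The rate is the percentage of flagged sites within `subset` (for example,
#' the sites known not to have attained the stage, making the rate a
#' false-flag rate).
#'
#' @param assignments a `stage_assignments`, or any data.frame with
#'   `site_id` and `category` columns.
#' @param stage category threshold.
#' @param subset character vector of site ids over which to compute the
#'   rate; default all sites.
#' @return list with `flags` (named logical over `subset`), `n_flagged`,
#'   `rate_pct`.
#' @export
flag_stage_attainment <- function(assignments, stage, subset = NULL) {
  stopifnot(all(c("site_id", "category") %in% names(assignments)))
  if (is.null(subset)) subset <- unique(assignments$site_id)
  if (length(subset) == 0L) stop("empty site subset")
  flags <- vapply(subset, function(s) {
    any(assignments$category[assignments$site_id == s] >= stage)
  }, logical(1))
  names(flags) <- subset
  list(flags = flags, n_flagged = sum(flags),
       rate_pct = 100 * sum(flags) / length(subset))
}

#' Maximum-likelihood Markov transition matrix over note sequences
#'
#' Counts consecutive note pairs `(a -> b)` within each site and
#' row-normalizes.  Rows whose state never occurs as a transition source are
#' left all-zero and reported in `empty_rows`.
#'
#' @param sequences either a list of integer category sequences (one per
#'   site) or a `stage_assignments` (split by site, note order).
#' @param n_categories number of states C; default the largest seen.
#' @param laplace additive smoothing count (default 0 = pure maximum
#'   likelihood).
#' @return object of class `transition_model`: list with `P` (C x C
#'   row-stochastic), `counts`, `n_transitions`, `empty_rows`.
#' @export
estimate_transition_matrix <- function(sequences, n_categories = NULL,
                                       laplace = 0) {
  if (inherits(sequences, "stage_assignments") || is.data.frame(sequences))
    sequences <- split(sequences$category, sequences$site_id)
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, as.integer)
  if (all(vapply(sequences, length, integer(1)) < 2L))
    stop("no sequence of length >= 2")
  C <- if (is.null(n_categories)) max(unlist(sequences)) else
    as.integer(n_categories)
  counts <- matrix(0, C, C, dimnames = list(from = seq_len(C),
                                            to = seq_len(C)))
  for (s in sequences) {
    if (length(s) < 2L) next
    for (j in seq_len(length(s) - 1L))
      counts[s[j], s[j + 1L]] <- counts[s[j], s[j + 1L]] + 1
  }
  sm <- counts + laplace
  rs <- rowSums(sm)
  P <- sm
  nz <- rs > 0
  P[nz, ] <- sm[nz, , drop = FALSE] / rs[nz]
  P[!nz, ] <- 0
  structure(list(P = P, counts = counts, n_transitions = sum(counts),
                 empty_rows = which(!nz)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Markov transition model over", nrow(x$P), "states;",
      x$n_transitions, "observed transitions\n")
  print(round(x$P, 3))
  invisible(x)
}

#' Write a transition matrix as a delimited table with a state header
#' @param model a `transition_model`.
#' @param path output CSV.
#' @export
write_transition_matrix <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  utils::write.csv(as.data.frame(model$P), path, row.names = FALSE)
  invisible(path)
}

#' Boundary-recovery rate of detected intervals against known truth
#'
#' For each true `(site, stage)` occupancy, checks whether some detected
#' interval for that stage has both boundaries within `tol_notes` note
#' positions of the true first/last note of the occupancy.
#'
#' @param trajectories a `stage_trajectories`.
#' @param truth_intervals data.frame with `site_id`, `stage`, `start_idx`,
#'   `end_idx` (note positions within the site's date-ordered notes).
#' @param tol_notes tolerance in note positions (default 1).
#' @return list with `n_true`, `n_recovered`, `rate` (fraction in `[0, 1]`),
#'   and the per-occupancy logical `recovered`.
#' @export
interval_recovery <- function(trajectories, truth_intervals, tol_notes = 1) {
  stopifnot(inherits(trajectories, "stage_trajectories"))
  rec <- vapply(seq_len(nrow(truth_intervals)), function(i) {
    tr <- trajectories[[as.character(truth_intervals$site_id[i])]]
    if (is.null(tr)) return(FALSE)
    iv <- tr$intervals
    iv <- iv[iv$stage == truth_intervals$stage[i], , drop = FALSE]
    if (nrow(iv) == 0L) return(FALSE)
    any(abs(iv$start_idx - truth_intervals$start_idx[i]) <= tol_notes &
          abs(iv$end_idx - truth_intervals$end_idx[i]) <= tol_notes)
  }, logical(1))
  list(n_true = length(rec), n_recovered = sum(rec),
       rate = if (length(rec)) mean(rec) else NA_real_, recovered = rec)
}
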
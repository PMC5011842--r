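# Synthetic corpus generator with known ground truth.
#
# Emulates the structure of a multi-site implementation log: per-stage
# vocabularies with controllable adjacent-stage overlap, per-site
# chronological trajectories that traverse stages in order (most sites
# stopping early), short bag-of-words notes with a background-noise word
# rate, a small labeled fraction, and a heavily imbalanced per-stage count
# distribution.  Words are pronounceable CVCV... strings ending in a
# consonant, chosen so that Porter stemming is a no-op on them; this
# isolates the selection/factorization pipeline from stemmer behavior while
# still exercising tokenization.

#' Configuration for the synthetic corpus generator
#'
#' Defaults mirror a forty-site implementation effort at roughly one-tenth
#' the scale of a multi-year trial: 4 stage categories, 40 sites of which a
#' fraction 31/40 never passes stage 3, about 460 notes, 10% of notes
#' expert-labeled, and description sentence counts of 8/9/12/47 across the
#' four categories.
#'
#' @param n_stages number of stages S (default 4, the collapsed
#'   four-category scheme).
#' @param n_sites number of sites (default 40).
#' @param notes_per_stage_min,notes_per_stage_lambda notes a site writes
#'   while occupying one stage: `min + Poisson(lambda)` (defaults 2 and 1.6,
#'   mean 3.6 so the default corpus has ~460 notes).
#' @param vocab_size words in each stage's vocabulary (default 15).
#' @param overlap_fraction fraction of `vocab_size` shared with each
#'   adjacent stage, in `[0, 0.5)` (default 0: disjoint vocabularies).
#' @param background_size size of the stage-neutral background vocabulary
#'   (default 30).
#' @param noise_rate probability that a note token is a background word
#'   rather than a stage word (default 0.15).
#' @param note_length_min,note_length_lambda tokens per note:
#'   `min + Poisson(lambda)` (defaults 8 and 6).
#' @param labeled_fraction fraction of notes carrying their true stage label
#'   (default 0.1).
#' @param stop_fraction probability that a site never advances beyond
#'   `stop_stage` (default 31/40).
#' @param stop_stage the stage early-stopping sites end at (default 3).
#' @param duration_shape,duration_scale gamma parameters for stage duration
#'   in days (defaults 4 and 22.5: mean 90 days).
#' @param n_descriptions integer vector (recycled to S) of description
#'   sentences per stage; default `c(8, 9, 12, 47)` when S = 4, else 10
#'   each.
#' @param desc_length_range range of words per description sentence.
#' @param start_date_range earliest/latest possible site start date.
#' @param seed integer seed governing every random draw.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_stages = 4, n_sites = 40,
                         notes_per_stage_min = 2,
                         notes_per_stage_lambda = 1.6,
                         vocab_size = 15, overlap_fraction = 0,
                         background_size = 30, noise_rate = 0.15,
                         note_length_min = 8, note_length_lambda = 6,
                         labeled_fraction = 0.1,
                         stop_fraction = 31 / 40, stop_stage = 3,
                         duration_shape = 4, duration_scale = 22.5,
                         n_descriptions = NULL,
                         desc_length_range = c(6, 12),
                         start_date_range = as.Date(c("2006-05-01",
                                                      "2007-12-31")),
                         seed = 1L) {
  stopifnot(n_stages >= 2, n_sites >= 1, vocab_size >= 1,
            overlap_fraction >= 0, overlap_fraction < 0.5,
            labeled_fraction >= 0, labeled_fraction <= 1,
            noise_rate >= 0, noise_rate < 1,
            stop_fraction >= 0, stop_fraction <= 1,
            stop_stage >= 1, stop_stage <= n_stages)
  if (is.null(n_descriptions))
    n_descriptions <- if (n_stages == 4) c(8L, 9L, 12L, 47L) else
      rep(10L, n_stages)
  n_descriptions <- rep_len(as.integer(n_descriptions), n_stages)
  stopifnot(all(n_descriptions >= 1))
  structure(as.list(environment()), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic corpus config:", x$n_stages, "stages,", x$n_sites,
      "sites, overlap", x$overlap_fraction, ", labeled fraction",
      x$labeled_fraction, ", seed", x$seed, "\n")
  invisible(x)
}

# pronounceable stem-stable synthetic words
.make_words <- function(n, rng_reserved = character(0)) {
  cons <- c("b", "d", "f", "g", "j", "l", "m", "n", "p", "r", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  finals <- c("k", "m", "n", "p", "r", "t")
  words <- character(0)
  while (length(words) < n) {
    syl <- sample(2:3, 1)
    w <- paste0(paste0(sample(cons, syl, TRUE), sample(vows, syl, TRUE),
                       collapse = ""), sample(finals, 1))
    if (w %in% words || w %in% rng_reserved) next
    if (porter_stem(w) != w) next           # guarantee stemming is a no-op
    words <- c(words, w)
  }
  words
}

#' Generate per-stage vocabularies
#'
#' Each stage receives `vocab_size` words: a core unique to it plus, for
#' each adjacent stage, `round(overlap_fraction * vocab_size)` words shared
#' with that neighbor.
#'
#' @param config a [synth_config()].  Drawing uses the current RNG state;
#'   call `set.seed(config$seed)` first (or use [generate_corpus()], which
#'   does).
#' @return list with `stage_vocab` (list of character vectors),
#'   `background` (character vector), `shared` (list of shared word sets per
#'   adjacent pair).
#' @export
generate_stage_vocabularies <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  S <- config$n_stages; V <- config$vocab_size
  n_share <- round(config$overlap_fraction * V)
  shared <- lapply(seq_len(S - 1), function(i) character(0))
  all_words <- character(0)
  if (n_share > 0) {
    for (i in seq_len(S - 1)) {
      shared[[i]] <- .make_words(n_share, all_words)
      all_words <- c(all_words, shared[[i]])
    }
  }
  stage_vocab <- vector("list", S)
  for (s in seq_len(S)) {
    with_prev <- if (s > 1) shared[[s - 1]] else character(0)
    with_next <- if (s < S) shared[[s]] else character(0)
    n_core <- V - length(with_prev) - length(with_next)
    if (n_core < 1)
      stop("overlap_fraction ", config$overlap_fraction,
           " leaves stage ", s, " without core words")
    core <- .make_words(n_core, all_words)
    all_words <- c(all_words, core)
    stage_vocab[[s]] <- c(with_prev, core, with_next)
  }
  background <- .make_words(config$background_size, all_words)
  list(stage_vocab = stage_vocab, background = background, shared = shared)
}

#' Generate one site's dated true-stage sequence
#'
#' Stages are visited in increasing order from 1; with probability
#' `stop_fraction` the site never advances beyond `stop_stage`.  Each
#' occupied stage lasts a gamma-distributed number of days and produces
#' `notes_per_stage_min + Poisson(notes_per_stage_lambda)` notes at sorted
#' uniform dates within the occupancy window.
#'
#' @param config a [synth_config()].
#' @param site_id site identifier string.
#' @param seed integer seed for this site's draws.
#' @return data.frame with columns `site_id`, `date`, `stage`, in
#'   chronological order.
#' @export
generate_site_trajectory <- function(config, site_id, seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  S <- config$n_stages
  final_stage <- if (stats::runif(1) < config$stop_fraction)
    config$stop_stage else S
  start <- config$start_date_range[1] +
    sample.int(as.integer(diff(config$start_date_range)) + 1L, 1L) - 1L
  rows <- list()
  day <- start
  for (s in seq_len(final_stage)) {
    dur <- max(7L, round(stats::rgamma(1, shape = config$duration_shape,
                                       scale = config$duration_scale)))
    n_notes <- config$notes_per_stage_min +
      stats::rpois(1, config$notes_per_stage_lambda)
    offs <- sort(sample.int(dur, min(n_notes, dur), replace = n_notes > dur))
    if (length(offs) < n_notes)
      offs <- sort(c(offs, sample.int(dur, n_notes - length(offs),
                                      replace = TRUE)))
    rows[[s]] <- data.frame(site_id = site_id, date = day + offs - 1L,
                            stage = s, stringsAsFactors = FALSE)
    day <- day + dur
  }
  do.call(rbind, rows)
}

.make_note_text <- function(vocab, background, config) {
  n_tok <- config$note_length_min + stats::rpois(1, config$note_length_lambda)
  from_bg <- stats::runif(n_tok) < config$noise_rate
  toks <- character(n_tok)
  toks[from_bg] <- sample(background, sum(from_bg), replace = TRUE)
  toks[!from_bg] <- sample(vocab, sum(!from_bg), replace = TRUE)
  paste(toks, collapse = " ")
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces a [log_corpus()] (with an extra `true_stage` column on its
#' notes), matching [stage_descriptions()] built from each stage's
#' vocabulary, and a truth object with per-note stages and per-site true
#' stage intervals.
#'
#' @param config a [synth_config()].
#' @param pin_category_counts optional integer vector of length S: exact
#'   per-stage note totals to generate (e.g. `c(781, 2937, 183, 688)`);
#'   site-stage note counts are rescaled to match.  An error is raised if a
#'   positive count is requested for a stage no site occupies.
#' @return list with `corpus`, `descriptions`, `truth` (list: `note_stage`,
#'   `intervals` data.frame with `site_id`, `stage`, `start`, `end`,
#'   `start_idx`, `end_idx`), and `vocabularies`.
#' @export
generate_corpus <- function(config, pin_category_counts = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(config$seed))
  vocabs <- generate_stage_vocabularies(config)
  S <- config$n_stages

  # descriptions: sentences over the full stage vocabulary
  descriptions <- stage_descriptions(lapply(seq_len(S), function(s) {
    vapply(seq_len(config$n_descriptions[s]), function(j) {
      len <- sample(seq(config$desc_length_range[1],
                        min(config$desc_length_range[2],
                            length(vocabs$stage_vocab[[s]]))), 1)
      paste(sample(vocabs$stage_vocab[[s]], len), collapse = " ")
    }, character(1))
  }))

  site_ids <- sprintf("site%02d", seq_len(config$n_sites))
  site_seeds <- config$seed + 1000L + seq_len(config$n_sites)
  traj <- lapply(seq_len(config$n_sites), function(i)
    generate_site_trajectory(config, site_ids[i], site_seeds[i]))
  notes <- do.call(rbind, traj)

  if (!is.null(pin_category_counts)) {
    pin_category_counts <- rep_len(as.integer(pin_category_counts), S)
    notes <- .pin_counts(notes, pin_category_counts, S)
  }

  set.seed(config$seed + 500L)
  notes$text <- vapply(notes$stage, function(s)
    .make_note_text(vocabs$stage_vocab[[s]], vocabs$background, config),
    character(1))
  n <- nrow(notes)
  notes$label <- NA_integer_
  n_lab <- round(config$labeled_fraction * n)
  if (n_lab > 0) {
    lab_idx <- sample.int(n, n_lab)
    notes$label[lab_idx] <- notes$stage[lab_idx]
  }

  corpus <- log_corpus(
    data.frame(site_id = notes$site_id, date = notes$date, text = notes$text,
               label = notes$label, stringsAsFactors = FALSE),
    n_stages = S)
  # re-attach the true stage in the corpus' (site, date)-sorted order
  ord <- order(notes$site_id, notes$date, seq_len(n), method = "radix")
  corpus$notes$true_stage <- notes$stage[ord]

  intervals <- do.call(rbind, lapply(split(corpus$notes, corpus$notes$site_id),
                                     function(df) {
    idx <- seq_len(nrow(df))
    do.call(rbind, lapply(sort(unique(df$true_stage)), function(s) {
      pos <- idx[df$true_stage == s]
      data.frame(site_id = df$site_id[1], stage = s,
                 start = df$date[min(pos)], end = df$date[max(pos)],
                 start_idx = min(pos), end_idx = max(pos),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(intervals) <- NULL

  list(corpus = corpus, descriptions = descriptions,
       truth = list(note_stage = corpus$notes$true_stage,
                    intervals = intervals),
       vocabularies = vocabs)
}

# Rescale site-stage note counts so each stage's total matches the target.
.pin_counts <- function(notes, targets, S) {
  out <- list()
  for (s in seq_len(S)) {
    idx <- which(notes$stage == s)
    tgt <- targets[s]
    if (tgt == 0L) next
    if (length(idx) == 0L)
      stop("pinned count ", tgt, " requested for stage ", s,
           " but no site occupies it")
    if (tgt <= length(idx)) {
      keep <- sort(sample(idx, tgt))
      out[[s]] <- notes[keep, , drop = FALSE]
    } else {
      extra <- sample(idx, tgt - length(idx), replace = TRUE)
      dup <- notes[extra, , drop = FALSE]
      dup$date <- dup$date + sample(0:3, nrow(dup), replace = TRUE)
      out[[s]] <- rbind(notes[idx, , drop = FALSE], dup)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
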
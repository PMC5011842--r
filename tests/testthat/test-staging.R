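make_assignments <- function(site_id, date, P) {
  colnames(P) <- paste0("p_", seq_len(ncol(P)))
  out <- data.frame(site_id = site_id, date = as.Date(date),
                    category = max.col(P, ties.method = "first"), P,
                    stringsAsFactors = FALSE)
  attr(out, "prob") <- P
  class(out) <- c("stage_assignments", "data.frame")
  out
}

test_that("argmax category uses the lowest index on ties; pooling sums columns", {
  expect_equal(collapse_probabilities(rbind(c(0.1, 0.2, 0.3, 0.4)), NULL),
               rbind(c(0.1, 0.2, 0.3, 0.4)))
  row8 <- matrix(rep(0.125, 8), 1)
  pooled <- collapse_probabilities(row8, 4)
  expect_equal(ncol(pooled), 4L)
  expect_equal(pooled[1, 4], 0.625)
  expect_equal(sum(pooled), 1)

  P <- rbind(c(0.1, 0.2, 0.3, 0.4), rep(0.25, 4))
  expect_equal(max.col(P, ties.method = "first"), c(4L, 1L))
})

test_that("classify_notes aligns F rows with the corpus and drops extra rows", {
  corpus <- log_corpus(tiny_notes(), n_stages = 4)
  p <- random_problem(1, L = 7, K = 5, S = 4)   # 5 notes + 2 appended docs
  fit <- fit_semi_nmf(p$X, p$constraints, max_iter = 20, tol = 0, seed = 1)
  asg <- classify_notes(fit, corpus)
  expect_equal(nrow(asg), 5L)
  expect_equal(attr(asg, "prob"), unname(fit$F[1:5, ]), ignore_attr = TRUE)
  short <- fit_semi_nmf(p$X[1:3, ], label_constraints(rep(NA_integer_, 3),
                                                      p$keyword_labels, 4),
                        max_iter = 5, tol = 0, seed = 1)
  expect_error(classify_notes(short, corpus), "corpus has")
})

test_that("evaluation metrics match base-R cross tabulation on random pairs", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:60, 1); C <- sample(2:5, 1)
    truth <- sample(C, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth, sample(C, n, replace = TRUE))
    rep_ <- evaluate_predictions(pred, truth, n_categories = C)
    tab <- table(factor(truth, 1:C), factor(pred, 1:C))
    expect_equal(unclass(rep_$confusion), unclass(tab), ignore_attr = TRUE)
    expect_equal(rep_$accuracy, mean(pred == truth))
    expect_equal(sum(rep_$confusion), n)
  }
  expect_error(evaluate_predictions(integer(0), integer(0)), "no predictions")
  expect_error(evaluate_predictions(1:3, 1:2), "length")
})

test_that("interval detection equals exhaustive run scanning (all length-12 sequences)", {
  dates <- as.Date("2008-01-01") + 0:11
  n_checked <- 0L
  mismatches <- integer(0)
  for (min_run in c(1, 2, 3)) {
    for (code in 0:(2^12 - 1)) {
      above <- as.logical(bitwAnd(bitwShiftR(code, 0:11), 1L))
      prob <- ifelse(above, 0.9, 0.1)
      got <- detect_stage_interval(dates, prob, threshold = 0.5,
                                   min_run = min_run)
      want <- runscan_oracle(above, min_run)
      ok <- if (is.null(want)) nrow(got) == 0L else
        identical(got$start_idx, as.integer(want[, 1])) &&
        identical(got$end_idx, as.integer(want[, 2])) &&
        identical(got$start, dates[want[, 1]]) &&
        identical(got$end, dates[want[, 2]])
      if (!ok) mismatches <- c(mismatches, code)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 3L * 4096L)
  expect_identical(mismatches, integer(0))
})

test_that("a sustained rise then fall brackets one interval", {
  dates <- as.Date("2008-01-01") + 0:5
  p <- c(0.1, 0.1, 0.9, 0.9, 0.9, 0.1)
  iv <- detect_stage_interval(dates, p, threshold = 0.5, min_run = 2)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, dates[3])
  expect_equal(iv$end, dates[5])
  expect_equal(nrow(detect_stage_interval(dates, rep(0.2, 6))), 0L)
})

test_that("smoothing bridges a one-note dip", {
  dates <- as.Date("2008-01-01") + 0:6
  p <- c(0.9, 0.9, 0.2, 0.9, 0.9, 0.1, 0.1)
  raw <- detect_stage_interval(dates, p, min_run = 2)
  expect_equal(nrow(raw), 2L)
  sm <- detect_stage_interval(dates, p, min_run = 2, smooth_window = 3)
  expect_equal(nrow(sm), 1L)
})

test_that("attainment flags are monotone in added notes", {
  asg <- make_assignments(
    c("A", "A", "B", "C"), rep("2008-01-01", 4),
    rbind(c(0, 0, 0, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0)))
  fl <- flag_stage_attainment(asg, stage = 4)
  expect_identical(unname(fl$flags), c(TRUE, FALSE, FALSE))
  expect_equal(fl$rate_pct, 100 / 3)
  # adding a stage-4 note to site B can only add flags
  asg2 <- make_assignments(
    c("A", "A", "B", "B", "C"), rep("2008-01-01", 5),
    rbind(c(0, 0, 0, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1),
          c(0, 1, 0, 0)))
  fl2 <- flag_stage_attainment(asg2, stage = 4)
  expect_true(all(fl$flags[fl$flags] <= fl2$flags[names(fl$flags)[fl$flags]]))
  expect_gte(fl2$n_flagged, fl$n_flagged)
  expect_error(flag_stage_attainment(asg, 4, subset = character(0)), "empty")
})

test_that("transition counts and probabilities follow maximum likelihood", {
  tm <- estimate_transition_matrix(list(c(1, 1, 1, 2)), n_categories = 2)
  expect_equal(tm$P[1, ], c(2 / 3, 1 / 3), ignore_attr = TRUE)
  expect_equal(tm$counts[1, ], c(2, 1), ignore_attr = TRUE)
  expect_equal(tm$n_transitions, 3)
  expect_identical(unname(tm$empty_rows), 2L)  # state 2 never a source

  const <- estimate_transition_matrix(list(c(3, 3, 3)), n_categories = 3)
  expect_equal(const$P[3, 3], 1)
  # rows with counts sum to exactly 1
  set.seed(4)
  seqs <- lapply(1:6, function(i) sample(4, 10, replace = TRUE))
  tm2 <- estimate_transition_matrix(seqs, n_categories = 4)
  has <- rowSums(tm2$counts) > 0
  expect_true(all(rowSums(tm2$P)[has] == 1))
  expect_true(all(tm2$P >= 0 & tm2$P <= 1))
  expect_error(estimate_transition_matrix(list(1L, 2L)), "length >= 2")
  # Laplace smoothing fills empty rows
  tm3 <- estimate_transition_matrix(list(c(1, 1)), n_categories = 2,
                                    laplace = 1)
  expect_equal(rowSums(tm3$P), c(1, 1), ignore_attr = TRUE)
})

test_that("site trajectories collect per-stage intervals and recovery works", {
  P <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9),
             c(0.9, 0.1), c(0.7, 0.3))
  asg <- make_assignments(rep(c("A", "B"), each = 3),
                          as.Date("2008-01-01") + c(0:2, 0:2), P)
  tr <- site_trajectories(asg, threshold = 0.5, min_run = 2)
  expect_named(tr, c("A", "B"))
  expect_equal(tr$A$intervals$stage, 1L)
  expect_equal(tr$A$intervals$start_idx, 1L)
  expect_equal(tr$A$intervals$end_idx, 2L)
  truth <- data.frame(site_id = c("A", "B"), stage = c(1L, 1L),
                      start_idx = c(1L, 2L), end_idx = c(3L, 3L))
  rec <- interval_recovery(tr, truth, tol_notes = 1)
  expect_equal(rec$n_true, 2L)
  expect_equal(rec$recovered, c(TRUE, TRUE))
})
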
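# Shared fixture builders and independent oracles.

# small hand-written corpus data.frame
tiny_notes <- function() {
  data.frame(
    site_id = c("A", "A", "A", "B", "B"),
    date = as.Date(c("2008-01-05", "2008-02-01", "2008-03-10",
                     "2007-11-20", "2008-01-15")),
    text = c("agreement to consider adoption",
             "planning the referral process",
             "training schedule drafted",
             "first contact for planning",
             "referral review meeting"),
    label = c(1L, 2L, NA, 1L, NA),
    stringsAsFactors = FALSE)
}

tiny_descriptions <- function() {
  stage_descriptions(list(
    c("agreement to consider implementation", "first contact made"),
    c("planning and preparation for implementation", "readiness planning"),
    c("referral process review", "recruitment plan and review"),
    c("training schedule set", "training for certification")))
}

# random semi-NMF problem of the standard test shape
random_problem <- function(seed, L = 60, K = 25, S = 4,
                           labeled_notes = 0.1, labeled_keywords = 0.3) {
  set.seed(seed)
  X <- matrix(runif(L * K), L, K)
  X <- X / rowSums(X)
  note_lab <- rep(NA_integer_, L)
  idx <- sample(L, round(labeled_notes * L))
  note_lab[idx] <- sample(S, length(idx), replace = TRUE)
  kw_lab <- rep(NA_integer_, K)
  idxk <- sample(K, round(labeled_keywords * K))
  kw_lab[idxk] <- sample(S, length(idxk), replace = TRUE)
  list(X = X, constraints = label_constraints(note_lab, kw_lab, S),
       note_labels = note_lab, keyword_labels = kw_lab, S = S)
}

# elementwise-summation oracle for the factorization objective
objective_oracle <- function(X, F, H, G, constraints) {
  FHGt <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      for (a in seq_len(ncol(F)))
        for (b in seq_len(ncol(F)))
          FHGt[i, j] <- FHGt[i, j] + F[i, a] * H[a, b] * G[j, b]
  tot <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      tot <- tot + (X[i, j] - FHGt[i, j])^2
  for (i in seq_len(nrow(F)))
    if (constraints$c0[i] == 1)
      for (a in seq_len(ncol(F)))
        tot <- tot + constraints$alpha * (F[i, a] - constraints$F0[i, a])^2
  for (i in seq_len(nrow(G)))
    if (constraints$c1[i] == 1)
      for (a in seq_len(ncol(G)))
        tot <- tot + constraints$beta * (G[i, a] - constraints$G0[i, a])^2
  tot
}

# Brute-force scores for greedy max-relevance/min-redundancy selection,
# written independently of the package internals (recomputes every cosine
# from scratch at every step).  Returns the score of every candidate given
# the stems already chosen.
mrmr_oracle_scores <- function(counts, doc_totals, chosen) {
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cand <- setdiff(sort(rownames(counts)), chosen)
  vapply(cand, function(w) {
    rel <- cos(counts[w, ], doc_totals)
    red <- 0
    if (length(chosen) > 0) {
      for (p in chosen) red <- red + cos(counts[w, ], counts[p, ])
      red <- red / length(chosen)
    }
    rel - red
  }, numeric(1))
}

# Checks that a selection sequence is greedy-optimal step by step: every
# pick attains the oracle's best achievable score among the remaining
# candidates (ties between mathematically equal scores are allowed to
# resolve either way).
expect_greedy_optimal <- function(selection, counts, doc_totals) {
  chosen <- character(0)
  for (w in selection) {
    scores <- mrmr_oracle_scores(counts, doc_totals, chosen)
    expect_true(w %in% names(scores))
    expect_gte(scores[[w]], max(scores) - 1e-12)
    chosen <- c(chosen, w)
  }
  invisible(TRUE)
}

# brute-force run scanner for interval detection on a binary above-threshold
# sequence
runscan_oracle <- function(above, min_run) {
  out <- NULL
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) out <- rbind(out, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# minimal two-factor NMF (multiplicative updates), used as a generic
# reconstruction-error baseline
nmf_baseline <- function(X, rank, iters = 2000, seed = 1) {
  set.seed(seed)
  L <- nrow(X); K <- ncol(X)
  W <- matrix(runif(L * rank, 0.1, 1.1), L, rank)
  Hm <- matrix(runif(rank * K, 0.1, 1.1), rank, K)
  eps <- 1e-12
  for (it in seq_len(iters)) {
    W <- W * (X %*% t(Hm)) / (W %*% Hm %*% t(Hm) + eps)
    Hm <- Hm * (t(W) %*% X) / (t(W) %*% W %*% Hm + eps)
  }
  sum((X - W %*% Hm)^2)
}
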
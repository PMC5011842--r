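test_that("label constraints build one-hot rows with matching masks", {
  con <- label_constraints(c(2L, NA, 1L), c(NA, 3L), n_stages = 3)
  expect_equal(con$F0, rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(con$G0, rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(con$c0, c(1, 0, 1))
  expect_equal(con$c1, c(0, 1))
  expect_error(label_constraints(c(4L), c(NA), n_stages = 3), "outside")
  expect_error(label_constraints(c(1L), c(1L), 3, alpha = 0))
})

test_that("objective equals the elementwise summation oracle", {
  p <- random_problem(101, L = 6, K = 4, S = 2, labeled_notes = 0.5,
                      labeled_keywords = 0.5)
  set.seed(11)
  F <- matrix(runif(6 * 2), 6, 2)
  H <- matrix(runif(4), 2, 2)
  G <- matrix(runif(4 * 2), 4, 2)
  expect_equal(objective_value(p$X, F, H, G, p$constraints),
               objective_oracle(p$X, F, H, G, p$constraints),
               tolerance = 1e-10)
})

test_that("objective reduces to reconstruction error without labels, zero at a perfect fit", {
  set.seed(3)
  S <- 2
  F <- matrix(runif(5 * S), 5, S); H <- diag(S); G <- matrix(runif(3 * S), 3, S)
  X <- F %*% H %*% t(G)
  no_labels <- label_constraints(rep(NA_integer_, 5), rep(NA_integer_, 3), S)
  expect_equal(objective_value(X, F, H, G, no_labels), 0, tolerance = 1e-12)
  X2 <- X + 0.1
  expect_equal(objective_value(X2, F, H, G, no_labels),
               sum((X2 - F %*% H %*% t(G))^2), tolerance = 1e-10)
})

test_that("a single R update step matches one compiled sweep", {
  p <- random_problem(7)
  set.seed(8)
  F <- matrix(runif(60 * 4, 0.1, 1.1), 60, 4)
  H <- diag(4) + 0.1
  G <- matrix(runif(25 * 4, 0.1, 1.1), 25, 4)
  stepped <- update_step(p$X, F, H, G, p$constraints)
  res <- stagecast:::.seminmf_loop(p$X, F, H, G, p$constraints$F0,
                                   p$constraints$G0, p$constraints$c0,
                                   p$constraints$c1, 1, 1, 0, 1L, 1e-12,
                                   0L, 5L, 0)
  expect_equal(stepped$F, res$F, tolerance = 1e-12)
  expect_equal(stepped$H, res$H, tolerance = 1e-12)
  expect_equal(stepped$G, res$G, tolerance = 1e-12)
})

test_that("update steps keep factors non-negative and zeros absorbing", {
  p <- random_problem(21)
  set.seed(9)
  F <- matrix(runif(60 * 4, 0.1, 1.1), 60, 4)
  F[3, 2] <- 0
  H <- diag(4) + 0.1
  G <- matrix(runif(25 * 4, 0.1, 1.1), 25, 4)
  for (it in 1:100) {
    st <- update_step(p$X, F, H, G, p$constraints)
    F <- st$F; H <- st$H; G <- st$G
    expect_true(min(F) >= 0 && min(H) >= 0 && min(G) >= 0)
  }
  expect_identical(F[3, 2], 0)
})

test_that("one gradient-rule update never increases the objective (50 seeded problems)", {
  worst <- 0
  for (s in 1:50) {
    p <- random_problem(s)
    set.seed(s + 777)
    F <- matrix(runif(60 * 4, 0.1, 1.1), 60, 4)
    H <- diag(4) + 0.1
    G <- matrix(runif(25 * 4, 0.1, 1.1), 25, 4)
    before <- objective_value(p$X, F, H, G, p$constraints)
    st <- update_step(p$X, F, H, G, p$constraints)
    after <- objective_value(p$X, st$F, st$H, st$G, p$constraints)
    worst <- max(worst, (after - before) / before)
  }
  expect_lt(worst, 1e-8)
})

test_that("the fit honours the iteration contract and records a trace", {
  p <- random_problem(31)
  fit <- fit_semi_nmf(p$X, p$constraints, max_iter = 5, tol = 0, seed = 1)
  expect_equal(fit$iterations, 5L)
  expect_length(fit$objective_trace, 6L)  # initial value + one per sweep
  expect_false(fit$converged)
  # rows of the normalized factors are probability vectors
  expect_equal(rowSums(fit$F), rep(1, 60), tolerance = 1e-9)
  expect_equal(rowSums(fit$G), rep(1, 25), tolerance = 1e-9)
})

test_that("identical seeds reproduce identical factorizations", {
  p <- random_problem(5)
  f1 <- fit_semi_nmf(p$X, p$constraints, max_iter = 50, tol = 0, seed = 42)
  f2 <- fit_semi_nmf(p$X, p$constraints, max_iter = 50, tol = 0, seed = 42)
  expect_identical(f1$F, f2$F)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$G, f2$G)
  f3 <- fit_semi_nmf(p$X, p$constraints, max_iter = 50, tol = 0, seed = 43)
  expect_false(identical(f1$F, f3$F))
})

test_that("KKT residual vanishes at a constructed stationary point", {
  set.seed(12)
  S <- 3
  F <- matrix(runif(8 * S, 0.2, 1), 8, S)
  H <- diag(S)
  G <- matrix(runif(5 * S, 0.2, 1), 5, S)
  X <- F %*% H %*% t(G)
  # labeled rows agree exactly with F, so the penalty gradient is zero too
  lab <- rep(NA_integer_, 8)
  con <- label_constraints(lab, rep(NA_integer_, 5), S)
  expect_lt(kkt_residual(X, F, H, G, con), 1e-10)
})

test_that("unsupervised fit matches a generic NMF reconstruction baseline", {
  set.seed(77)
  S <- 3
  Wtrue <- matrix(rexp(40 * S), 40, S)
  Htrue <- matrix(rexp(S * 12), S, 12)
  X <- Wtrue %*% Htrue + matrix(runif(40 * 12, 0, 0.01), 40, 12)
  con <- label_constraints(rep(NA_integer_, 40), rep(NA_integer_, 12), S)
  fit <- fit_semi_nmf(X, con, max_iter = 5000, tol = 1e-12, seed = 3)
  err_tri <- sum((X - fit$F_raw %*% fit$H %*% t(fit$G_raw))^2)
  err_two <- nmf_baseline(X, S, iters = 5000, seed = 3)
  expect_lt(err_tri, err_two * 1.05)
})

test_that("block-structured data with 10% one-hot labels is recovered", {
  # three disjoint keyword groups generate three note blocks
  set.seed(55)
  S <- 3; per_block <- 30; K <- 12
  block_of_note <- rep(1:S, each = per_block)
  block_of_kw <- rep(1:S, each = K / S)
  L <- length(block_of_note)
  X <- matrix(0, L, K)
  for (i in seq_len(L)) {
    cols <- which(block_of_kw == block_of_note[i])
    cnt <- rpois(length(cols), 2) + 1
    X[i, cols] <- cnt / sum(cnt)
  }
  labels <- rep(NA_integer_, L)
  lab_idx <- sample(L, round(0.1 * L))
  labels[lab_idx] <- block_of_note[lab_idx]
  con <- label_constraints(labels, rep(NA_integer_, K), S)
  fit <- fit_semi_nmf(X, con, max_iter = 3000, tol = 1e-9, seed = 5)
  pred <- max.col(fit$F, ties.method = "first")
  # the stage indices recovered must match the generating blocks up to the
  # labeled anchoring, which pins the permutation
  expect_gte(mean(pred == block_of_note), 0.95)
})

test_that("the orthogonal-rule variant runs but is not gradient-stationary", {
  p <- random_problem(13)
  fit <- fit_semi_nmf(p$X, p$constraints, max_iter = 2000, tol = 1e-9,
                      seed = 2, update_rule = "orthogonal")
  expect_true(all(fit$F_raw >= 0) && all(fit$G_raw >= 0))
  # its fixed point coincides with the objective's KKT point only under
  # column orthonormality, so the plain-gradient residual stays large
  expect_gt(fit$kkt_residual_F, 1e-2)
})

test_that("dimension mismatches are rejected", {
  p <- random_problem(2)
  F <- matrix(1, 60, 4); H <- diag(4); G <- matrix(1, 24, 4)
  expect_error(objective_value(p$X, F, H, G, p$constraints),
               "dimension mismatch")
})
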
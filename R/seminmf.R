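# Semi-supervised non-negative tri-factorization X ~ F H G'.
#
# X is the L x K row-normalized note-keyword matrix; F (L x S) carries
# note-to-stage probabilities, G (K x S) keyword-to-stage probabilities, and
# H (S x S) the stage-correlation core.  Partial labels enter through F0/G0
# (one-hot rows) masked by diagonal indicators C0/C1 and weighted by
# alpha/beta: the objective is
#
#   ||X - F H G'||^2 + alpha tr((F-F0)' C0 (F-F0)) + beta tr((G-G0)' C1 (G-G0))
#
# minimized by multiplicative updates (see fit_semi_nmf for the two
# denominator variants).

#' Assemble partial-label constraints
#'
#' Builds the one-hot indicator matrices `F0` (notes) and `G0` (keywords) and
#' their diagonal masks from integer label vectors, with `NA` meaning
#' unlabeled.
#'
#' @param note_labels integer vector of length L; stage in `1..n_stages` or
#'   `NA`.
#' @param keyword_labels integer vector of length K; stage or `NA`.
#' @param n_stages number of stages S.
#' @param alpha,beta positive supervision weights for notes and keywords.
#'   Default 1, appropriate when the expert labels are trusted; lower values
#'   soften the pull towards noisy labels.
#' @return object of class `label_constraints`: list with `F0`, `G0`, `c0`,
#'   `c1` (diagonal 0/1 vectors), `alpha`, `beta`, `n_stages`.
#' @export
label_constraints <- function(note_labels, keyword_labels, n_stages,
                              alpha = 1, beta = 1) {
  stopifnot(alpha > 0, beta > 0, n_stages >= 2)
  one_hot <- function(labels) {
    M <- matrix(0, length(labels), n_stages)
    idx <- which(!is.na(labels))
    if (any(labels[idx] < 1 | labels[idx] > n_stages))
      stop("label outside 1..", n_stages)
    M[cbind(idx, labels[idx])] <- 1
    M
  }
  F0 <- one_hot(as.integer(note_labels))
  G0 <- one_hot(as.integer(keyword_labels))
  structure(list(F0 = F0, G0 = G0,
                 c0 = as.numeric(rowSums(F0) > 0),
                 c1 = as.numeric(rowSums(G0) > 0),
                 alpha = alpha, beta = beta,
                 n_stages = as.integer(n_stages)),
            class = "label_constraints")
}

#' @export
print.label_constraints <- function(x, ...) {
  cat("Label constraints:", sum(x$c0), "of", length(x$c0), "notes labeled;",
      sum(x$c1), "of", length(x$c1), "keywords labeled; alpha =", x$alpha,
      "beta =", x$beta, "\n")
  invisible(x)
}

check_dims <- function(X, F, H, G, constraints) {
  S <- constraints$n_stages
  if (!all(dim(F) == c(nrow(X), S)) || !all(dim(H) == c(S, S)) ||
      !all(dim(G) == c(ncol(X), S)) ||
      !all(dim(constraints$F0) == dim(F)) ||
      !all(dim(constraints$G0) == dim(G)))
    stop("dimension mismatch: X is ", nrow(X), "x", ncol(X),
         ", F ", nrow(F), "x", ncol(F), ", H ", nrow(H), "x", ncol(H),
         ", G ", nrow(G), "x", ncol(G))
  invisible(TRUE)
}

#' Objective value of the semi-supervised factorization
#'
#' @param X L x K non-negative matrix.
#' @param F,H,G current factors (L x S, S x S, K x S).
#' @param constraints a [label_constraints()].
#' @return the (non-negative) objective value.
#' @export
objective_value <- function(X, F, H, G, constraints) {
  check_dims(X, F, H, G, constraints)
  R <- X - F %*% H %*% t(G)
  sum(R^2) +
    constraints$alpha * sum(constraints$c0 * (F - constraints$F0)^2) +
    constraints$beta * sum(constraints$c1 * (G - constraints$G0)^2)
}

#' One multiplicative update sweep (F, then H, then G)
#'
#' Each factor is updated elementwise by a non-negative ratio, using the most
#' recent value of the others; denominators are stabilized by an additive
#' epsilon.  With `update_rule = "gradient"` the denominators are the
#' positive part of the objective's gradient, which makes the sweep a
#' majorization-minimization step: the objective never increases.  With
#' `update_rule = "orthogonal"` the F and G denominators take the
#' orthogonality-style form `F F' X G H'` / `G G' X' F H`; that variant is
#' only stationary where F and G have orthonormal columns and is provided
#' for comparison.
#'
#' @inheritParams objective_value
#' @param update_rule `"gradient"` (default) or `"orthogonal"`.
#' @param eps denominator stabilizer, default 1e-12.
#' @return list with updated `F`, `H`, `G`.
#' @export
update_step <- function(X, F, H, G, constraints,
                        update_rule = c("gradient", "orthogonal"),
                        eps = 1e-12) {
  update_rule <- match.arg(update_rule)
  check_dims(X, F, H, G, constraints)
  a <- constraints$alpha; b <- constraints$beta
  c0 <- constraints$c0; c1 <- constraints$c1
  F0 <- constraints$F0; G0 <- constraints$G0

  XG <- X %*% G
  GtG <- crossprod(G)
  numF <- XG %*% t(H) + a * c0 * F0
  denF <- if (update_rule == "gradient")
    F %*% (H %*% GtG %*% t(H)) else F %*% crossprod(F, XG %*% t(H))
  F <- F * numF / (denF + a * c0 * F + eps)

  FtF <- crossprod(F)
  H <- H * crossprod(F, X %*% G) / (FtF %*% H %*% GtG + eps)

  XtFH <- crossprod(X, F) %*% H
  numG <- XtFH + b * c1 * G0
  denG <- if (update_rule == "gradient")
    G %*% (t(H) %*% FtF %*% H) else G %*% crossprod(G, XtFH)
  G <- G * numG / (denG + b * c1 * G + eps)

  if (!all(is.finite(F)) || !all(is.finite(H)) || !all(is.finite(G)))
    stop("non-finite entry after update step")
  list(F = F, H = H, G = G)
}

#' Fit the semi-supervised tri-factorization
#'
#' Initializes strictly positive factors (uniform random in (0.1, 1.1); H at
#' identity + 0.1; labeled rows of F blended half-and-half with their one-hot
#' target), then iterates [update_step()] until the relative objective change
#' stays below `tol` for 5 consecutive iterations, or `max_iter` sweeps.
#' After convergence each row of `F` and `G` is normalized to sum to 1
#' (all-zero rows become uniform `1/S`); the un-normalized factors are kept
#' for diagnostics, and the KKT complementarity residual of F is evaluated on
#' them.
#'
#' @inheritParams objective_value
#' @param max_iter maximum update sweeps (default 500).
#' @param tol relative objective-change tolerance (default 1e-6); `tol = 0`
#'   always runs `max_iter` sweeps.
#' @param kkt_tol optional stationarity tolerance: when set, convergence
#'   additionally requires the scaled KKT complementarity residual of F to
#'   fall below this value (checked every 100 sweeps once the objective has
#'   stalled), so that `converged = TRUE` certifies a first-order stationary
#'   point rather than merely a flat objective.  Default `NULL` (objective
#'   stall only).
#' @param seed integer seed for the random initialization.
#' @param update_rule see [update_step()].
#' @param eps denominator stabilizer.
#' @return object of class `seminmf_fit`: list with row-normalized `F`, `G`,
#'   the core `H`, un-normalized `F_raw`/`G_raw`, `objective_trace` (one
#'   value per sweep, starting at the initial objective), `iterations`,
#'   `converged`, `kkt_residual_F` (scaled by `max(abs(X))`), and the fit
#'   settings.
#' @export
fit_semi_nmf <- function(X, constraints, max_iter = 500, tol = 1e-6,
                         kkt_tol = NULL, seed = 1L,
                         update_rule = c("gradient", "orthogonal"),
                         eps = 1e-12) {
  update_rule <- match.arg(update_rule)
  stopifnot(max_iter >= 1, tol >= 0, all(X >= 0))
  X <- as.matrix(X)
  S <- constraints$n_stages
  L <- nrow(X); K <- ncol(X)
  if (length(constraints$c0) != L || length(constraints$c1) != K)
    stop("constraints sized for ", length(constraints$c0), " notes and ",
         length(constraints$c1), " keywords; X is ", L, "x", K)
  set.seed(as.integer(seed))
  F <- matrix(stats::runif(L * S, 0.1, 1.1), L, S)
  G <- matrix(stats::runif(K * S, 0.1, 1.1), K, S)
  H <- diag(S) + 0.1
  lab <- constraints$c0 > 0
  F[lab, ] <- 0.5 * constraints$F0[lab, , drop = FALSE] +
    0.5 * F[lab, , drop = FALSE]

  res <- .seminmf_loop(X, F, H, G, constraints$F0, constraints$G0,
                       constraints$c0, constraints$c1,
                       constraints$alpha, constraints$beta,
                       tol, as.integer(max_iter), eps,
                       ifelse(update_rule == "gradient", 0L, 1L), 5L,
                       if (is.null(kkt_tol)) 0 else kkt_tol)

  kkt <- kkt_residual(X, res$F, res$H, res$G, constraints)
  normalize_rows <- function(M) {
    rs <- rowSums(M)
    zero <- rs <= 0
    M[!zero, ] <- M[!zero, , drop = FALSE] / rs[!zero]
    M[zero, ] <- 1 / ncol(M)
    M
  }
  structure(list(F = normalize_rows(res$F), H = res$H,
                 G = normalize_rows(res$G),
                 F_raw = res$F, G_raw = res$G,
                 objective_trace = res$objective_trace,
                 iterations = res$iterations, converged = res$converged,
                 kkt_residual_F = kkt, seed = as.integer(seed),
                 alpha = constraints$alpha, beta = constraints$beta,
                 tol = tol, update_rule = update_rule),
            class = "seminmf_fit")
}

#' @export
print.seminmf_fit <- function(x, ...) {
  cat("Semi-supervised NMF fit:", nrow(x$F), "notes x", nrow(x$G),
      "keywords ->", ncol(x$F), "stages\n")
  cat("  ", x$iterations, " iterations (",
      if (x$converged) "converged" else "max_iter reached", "), objective ",
      format(utils::tail(x$objective_trace, 1), digits = 6),
      ", scaled KKT residual ", format(x$kkt_residual_F, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' KKT complementarity residual for F
#'
#' At a local optimum every entry of F satisfies
#' `gradient_F(i,k) * F(i,k) = 0` (a zero entry may have positive gradient; a
#' positive entry must have zero gradient).  The residual is the largest
#' absolute violation, divided by `max(abs(X))` so that it is comparable
#' across problem scales.  Evaluate it on un-normalized factors (`F_raw`,
#' `G_raw` of a fit): row normalization moves the factors off the stationary
#' point.
#'
#' @inheritParams objective_value
#' @return non-negative scaled residual.
#' @export
kkt_residual <- function(X, F, H, G, constraints) {
  check_dims(X, F, H, G, constraints)
  grad <- -2 * X %*% G %*% t(H) +
    2 * F %*% (H %*% crossprod(G) %*% t(H)) +
    2 * constraints$alpha * constraints$c0 * (F - constraints$F0)
  max(abs(grad * F)) / max(abs(X))
}

#' Persist a fit's factors as delimited text with a metadata header
#'
#' @param fit a `seminmf_fit`.
#' @param path output file.
#' @export
write_factors <- function(fit, path) {
  stopifnot(inherits(fit, "seminmf_fit"))
  con <- file(path, "w"); on.exit(close(con))
  meta <- sprintf(
    "# stagecast seminmf_fit L=%d K=%d S=%d alpha=%g beta=%g seed=%d iterations=%d objective=%.15g",
    nrow(fit$F), nrow(fit$G), ncol(fit$F), fit$alpha, fit$beta, fit$seed,
    fit$iterations, utils::tail(fit$objective_trace, 1))
  writeLines(meta, con)
  for (nm in c("F", "H", "G")) {
    writeLines(paste0("# ", nm), con)
    utils::write.table(fit[[nm]], con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
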
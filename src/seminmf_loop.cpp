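// Multiplicative-update iteration loop for the semi-supervised
// tri-factorization  min ||X - F H G'||^2
//                      + alpha * tr((F-F0)' C0 (F-F0))
//                      + beta  * tr((G-G0)' C1 (G-G0)).
//
// Two denominator variants:
//   rule = 0 ("gradient"): exact-gradient majorization denominators
//       F <- F .* (X G H' + a C0 F0) ./ (F H G'G H' + a C0 F)
//       H <- H .* (F' X G)           ./ (F'F H G'G)
//       G <- G .* (X' F H + b C1 G0) ./ (G H'F'F H + b C1 G)
//     These are monotone for the objective and have the objective's KKT
//     point as their fixed point.
//   rule = 1 ("orthogonal"): the orthogonality-style denominators
//       (F F' X G H' + a C0 F) and (G G' X' F H + b C1 G),
//     inherited from orthogonal tri-factorization; kept for comparison.
//
// C0 and C1 are passed as diagonal 0/1 vectors.  Convergence: relative
// objective change below tol on `stall` consecutive iterations; when
// kkt_tol > 0, additionally the scaled KKT complementarity residual of F
// (max |grad_F .* F| / max |X|, checked every 100 iterations once the
// objective has stalled) must fall below kkt_tol, so that "converged"
// certifies first-order stationarity and not merely a flat objective.
//
// Only two L*K-sized products are formed per sweep (X G and X' F); the
// reconstruction term of the objective is evaluated through the trace
// identity ||X - F H G'||^2 = ||X||^2 - 2 tr((X'F) H G') + tr((G M) ' G)
// with M = H' F'F H, reusing factors already needed by the updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat maskrows(const mat& M, const vec& c) {
  mat R = M;
  R.each_col() %= c;
  return R;
}

static double penalty(const mat& F, const mat& F0, const vec& c0,
                      const mat& G, const mat& G0, const vec& c1,
                      double alpha, double beta) {
  mat DF = F - F0;
  DF.each_col() %= sqrt(c0);
  mat DG = G - G0;
  DG.each_col() %= sqrt(c1);
  return alpha * accu(square(DF)) + beta * accu(square(DG));
}

// [[Rcpp::export(name = ".seminmf_loop")]]
Rcpp::List seminmf_loop(const arma::mat& X, arma::mat F, arma::mat H,
                        arma::mat G, const arma::mat& F0,
                        const arma::mat& G0, const arma::vec& c0,
                        const arma::vec& c1, double alpha, double beta,
                        double tol, int max_iter, double eps, int rule,
                        int stall, double kkt_tol) {
  const double maxX = X.max();
  const double normX2 = accu(square(X));
  std::vector<double> trace;
  trace.reserve(std::min(max_iter + 1, 1 << 21));
  double obj = normX2 - 2.0 * accu((X.t() * F * H) % G) +
               accu((G * (H.t() * F.t() * F * H)) % G) +
               penalty(F, F0, c0, G, G0, c1, alpha, beta);
  trace.push_back(obj);
  int it = 0, stalled = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    const mat XG = X * G;                     // L x S (big gemm #1)
    const mat GtG = G.t() * G;
    const mat XGHt = XG * H.t();
    mat numF = XGHt + alpha * maskrows(F0, c0);
    mat denF;
    if (rule == 0) {
      denF = F * (H * GtG * H.t());
    } else {
      denF = F * (F.t() * XGHt);
    }
    denF += alpha * maskrows(F, c0);
    F %= numF / (denF + eps);

    const mat FtF = F.t() * F;
    H %= (F.t() * XG) / (FtF * H * GtG + eps);

    const mat XtF = X.t() * F;                // K x S (big gemm #2)
    const mat XtFH = XtF * H;
    const mat M = H.t() * FtF * H;            // S x S
    mat numG = XtFH + beta * maskrows(G0, c1);
    mat denG;
    if (rule == 0) {
      denG = G * M;
    } else {
      denG = G * (G.t() * XtFH);
    }
    denG += beta * maskrows(G, c1);
    G %= numG / (denG + eps);

    // zero is an absorbing state of the multiplicative update; flush entries
    // that have decayed to the denormal range to exact zero (avoids the
    // large hardware penalty of denormal arithmetic in later sweeps)
    F.clean(1e-250);
    H.clean(1e-250);
    G.clean(1e-250);

    if (!F.is_finite() || !H.is_finite() || !G.is_finite()) {
      Rcpp::stop("non-finite factor entry at iteration %d", it);
    }

    double obj2 = normX2 - 2.0 * accu(XtFH % G) + accu((G * M) % G) +
                  penalty(F, F0, c0, G, G0, c1, alpha, beta);
    trace.push_back(obj2);
    double denom = std::max(obj, 1e-300);
    if (std::abs(obj - obj2) < tol * denom) {
      ++stalled;
      bool done = stalled >= stall;
      if (done && kkt_tol > 0 && (stalled - stall) % 100 == 0) {
        const mat grad = -2.0 * (X * G) * H.t() +
                         2.0 * F * (H * (G.t() * G) * H.t()) +
                         2.0 * alpha * maskrows(F - F0, c0);
        done = abs(grad % F).max() / maxX <= kkt_tol;
      } else if (done && kkt_tol > 0) {
        done = false;  // between periodic stationarity checks
      }
      if (done) {
        obj = obj2;
        converged = true;
        break;
      }
    } else {
      stalled = 0;
    }
    obj = obj2;
  }

  return Rcpp::List::create(
      Rcpp::Named("F") = F, Rcpp::Named("H") = H, Rcpp::Named("G") = G,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("iterations") = std::min(it, max_iter),
      Rcpp::Named("converged") = converged);
}
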
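#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Dual of the Gaussian-sample projection QP used by the mean-field capacity
// estimator.  Primal: min_V 1/2 ||V - T||^2  s.t.  a_i' V >= kappa, with
// a_i = y_i * x_i (one signed, bias-augmented manifold point per row of A).
// Stationarity gives V = T + A' lambda, and the dual is the non-negative QP
//   min_{lambda >= 0} 1/2 lambda' G lambda - q' lambda,  G = A A',
//   q = kappa - A T.
// Solved by cyclic coordinate descent with an exact per-coordinate minimiser;
// G is PSD so the iteration is globally convergent.  The quantity averaged by
// the capacity formula is ||V - T||^2 = lambda' G lambda.

// Lawson-Hanson style active-set solver on the normal equations:
// min_{lam>=0} 1/2 lam'G lam - q'lam.  Used as an exact fallback when
// coordinate descent stalls on (near-)singular G.  Returns true on success.
static bool nnqp_active_set(const arma::mat& G, const arma::vec& q,
                            arma::vec& lam, const double tol) {
  const arma::uword m = G.n_rows;
  std::vector<bool> passive(m, false);
  lam.zeros(m);
  arma::vec g = -q;                       // gradient at lam = 0
  const double scale = 1.0 + arma::abs(q).max();
  for (arma::uword outer = 0; outer < 3 * m + 10; ++outer) {
    // most negative gradient among active (zero) coordinates
    int jbest = -1; double gbest = -tol * scale;
    for (arma::uword j = 0; j < m; ++j)
      if (!passive[j] && g[j] < gbest) { gbest = g[j]; jbest = j; }
    if (jbest < 0) return true;           // KKT satisfied
    passive[jbest] = true;
    for (arma::uword inner = 0; inner < m + 1; ++inner) {
      arma::uvec P(m); arma::uword np = 0;
      for (arma::uword j = 0; j < m; ++j) if (passive[j]) P[np++] = j;
      P.resize(np);
      arma::vec sol;
      bool ok = arma::solve(sol, G.submat(P, P), q.elem(P),
                            arma::solve_opts::likely_sympd +
                            arma::solve_opts::no_approx);
      if (!ok) sol = arma::pinv(G.submat(P, P)) * q.elem(P);
      if (sol.min() >= 0.0) {
        arma::vec lnew(m, arma::fill::zeros);
        lnew.elem(P) = sol;
        lam = lnew;
        break;
      }
      // step toward sol until the first passive coordinate hits zero
      double alpha = 1.0;
      for (arma::uword k = 0; k < np; ++k)
        if (sol[k] < 0.0) {
          double a = lam[P[k]] / (lam[P[k]] - sol[k]);
          if (a < alpha) alpha = a;
        }
      for (arma::uword k = 0; k < np; ++k) {
        lam[P[k]] += alpha * (sol[k] - lam[P[k]]);
        if (lam[P[k]] <= 1e-14) { lam[P[k]] = 0.0; passive[P[k]] = false; }
      }
    }
    g = G * lam - q;
  }
  return false;
}

// [[Rcpp::export]]
List nnqp_batch(const arma::mat& G, const arma::mat& Q,
                const int maxit = 20000, const double tol = 1e-8) {
  const arma::uword m = G.n_rows, ns = Q.n_cols;
  if (Q.n_rows != m) stop("Q must have as many rows as G");
  arma::vec diag = G.diag();
  arma::mat Lambda(m, ns, arma::fill::zeros);
  arma::vec F(ns), dualval(ns);
  arma::ivec iters(ns);
  arma::ivec conv(ns, arma::fill::zeros);

  for (arma::uword s = 0; s < ns; ++s) {
    arma::vec q = Q.col(s);
    arma::vec lam(m, arma::fill::zeros);
    arma::vec g = -q;               // gradient G*lam - q at lam = 0
    const double scale = 1.0 + arma::abs(q).max();
    int it = 0;
    for (; it < maxit; ++it) {
      for (arma::uword j = 0; j < m; ++j) {
        if (diag[j] <= 0.0) continue;  // degenerate zero row
        double lnew = lam[j] - g[j] / diag[j];
        if (lnew < 0.0) lnew = 0.0;
        double d = lnew - lam[j];
        if (d != 0.0) {
          g += d * G.col(j);
          lam[j] = lnew;
        }
      }
      // KKT on the end-of-sweep gradient: it must vanish on the support
      // and be non-negative off it
      double viol = 0.0;
      for (arma::uword j = 0; j < m; ++j) {
        if (diag[j] <= 0.0) continue;
        double v = (lam[j] > 0.0) ? std::abs(g[j]) : std::max(0.0, -g[j]);
        if (v > viol) viol = v;
      }
      if (viol < tol * scale) { conv[s] = 1; ++it; break; }
    }
    if (!conv[s]) {
      // coordinate descent can stall on (near-)singular G; fall back to an
      // exact active-set solve
      arma::vec lam2;
      if (nnqp_active_set(G, q, lam2, tol)) { lam = lam2; conv[s] = 1; }
    }
    iters[s] = it;
    double lgl = arma::dot(lam, G * lam);
    F[s] = lgl;                               // ||V - T||^2
    dualval[s] = -0.5 * lgl + arma::dot(q, lam);
    Lambda.col(s) = lam;
  }
  return List::create(_["F"] = F, _["lambda"] = Lambda,
                      _["dual"] = dualval, _["iters"] = iters,
                      _["converged"] = conv);
}
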
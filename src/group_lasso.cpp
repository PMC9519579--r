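// Block coordinate descent for a multi-context group LASSO:
//   min_B  sum_c ||y_c - X_c b_c||^2 / (2 n_c) + lambda * sum_m ||B[m,]||_2
// Each context c has its own design X_c (rows = that context's individuals,
// columns = the shared SNPs) and outcome y_c; a SNP's coefficient row is
// jointly zero or nonzero across contexts.
//
// The per-row update solves, given partial-residual correlations z_c and
// curvatures a_c = ||x_mc||^2/n_c,
//   min_b sum_c [ a_c/2 * b_c^2 - z_c b_c ] + lambda ||b||_2
// whose stationary point is b_c = z_c / (a_c + nu) with nu = lambda/||b||,
// found by safeguarded bisection on nu (contexts have unequal a_c, so there
// is no single closed form).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec solve_row(const arma::vec& z, const arma::vec& a,
                           double lambda) {
  const double znorm = arma::norm(z, 2);
  arma::vec b(z.n_elem, arma::fill::zeros);
  if (znorm <= lambda || lambda < 0) {
    if (lambda <= 0 && znorm > 0) {
      // unpenalized: b_c = z_c / a_c
      for (arma::uword c = 0; c < z.n_elem; ++c)
        b(c) = (a(c) > 0) ? z(c) / a(c) : 0.0;
      return b;
    }
    return b;
  }
  // t(nu) = sum_c (z_c * nu / (a_c + nu))^2 - lambda^2, increasing in nu
  auto tfun = [&](double nu) {
    double s = 0;
    for (arma::uword c = 0; c < z.n_elem; ++c) {
      double v = z(c) * nu / (a(c) + nu);
      s += v * v;
    }
    return s - lambda * lambda;
  };
  double lo = 1e-14, hi = 1.0;
  while (tfun(hi) < 0) { hi *= 2.0; if (hi > 1e12) break; }
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (tfun(mid) < 0) lo = mid; else hi = mid;
  }
  double nu = 0.5 * (lo + hi);
  for (arma::uword c = 0; c < z.n_elem; ++c) b(c) = z(c) / (a(c) + nu);
  return b;
}

// [[Rcpp::export]]
List gl_path_cpp(List X_list, List y_list, arma::vec lambdas,
                 double tol, int maxit) {
  const int C = X_list.size();
  std::vector<arma::mat> X(C);
  std::vector<arma::vec> y(C), res(C);
  for (int c = 0; c < C; ++c) {
    X[c] = as<arma::mat>(X_list[c]);
    y[c] = as<arma::vec>(y_list[c]);
    res[c] = y[c];
  }
  const arma::uword M = X[0].n_cols;
  arma::mat A(M, C);            // a_c(m) = ||x_mc||^2 / n_c
  arma::vec nvec(C);
  for (int c = 0; c < C; ++c) {
    nvec(c) = X[c].n_rows;
    for (arma::uword m = 0; m < M; ++m)
      A(m, c) = arma::dot(X[c].col(m), X[c].col(m)) / nvec(c);
  }
  const arma::uword L = lambdas.n_elem;
  arma::cube B(M, C, L, arma::fill::zeros);
  arma::mat b(M, C, arma::fill::zeros);
  LogicalVector converged(L);

  auto update_row = [&](arma::uword m, double lambda) -> double {
    arma::vec z(C), aa = A.row(m).t();
    for (int c = 0; c < C; ++c)
      z(c) = arma::dot(X[c].col(m), res[c]) / nvec(c) + aa(c) * b(m, c);
    arma::vec bn = solve_row(z, aa, lambda);
    double maxdel = 0.0;
    for (int c = 0; c < C; ++c) {
      double del = bn(c) - b(m, c);
      if (del != 0.0) {
        res[c] -= X[c].col(m) * del;
        b(m, c) = bn(c);
        double ad = std::abs(del);
        if (ad > maxdel) maxdel = ad;
      }
    }
    return maxdel;
  };

  for (arma::uword l = 0; l < L; ++l) {
    const double lambda = lambdas(l);
    bool ok = false;
    int pass = 0;
    while (pass < maxit) {
      // full sweep over all rows, collecting the active set
      double maxdel = 0.0;
      std::vector<arma::uword> active;
      for (arma::uword m = 0; m < M; ++m) {
        double d = update_row(m, lambda);
        if (d > maxdel) maxdel = d;
        if (arma::any(b.row(m) != 0.0)) active.push_back(m);
      }
      ++pass;
      if (maxdel < tol) { ok = true; break; }
      // cheap sweeps restricted to the active rows
      while (pass < maxit) {
        double adel = 0.0;
        for (arma::uword m : active) {
          double d = update_row(m, lambda);
          if (d > adel) adel = d;
        }
        ++pass;
        if (adel < tol) break;
      }
    }
    converged(l) = ok;
    B.slice(l) = b;
  }
  return List::create(_["beta"] = B, _["converged"] = converged);
}
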
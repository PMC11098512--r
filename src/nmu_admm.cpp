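// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "decay.h"
using namespace Rcpp;

// ADMM inner loop for the rank-one constrained NMU subproblem. Operates on
// the already max-scaled matrix Ys; all bookkeeping (scaling, SVD
// initialization, final exact projection of v) lives in the R wrapper.
//
// Split: (Ys + slack) - u v' = R >= 0 (relaxed underapproximation),
//        q = v with F(gamma) q <= 0 from `start` (1-based) on.
// [[Rcpp::export]]
List nmu_admm_cpp(const arma::mat& Ys, arma::vec u, arma::rowvec v,
                  bool update_u, bool has_constraint, double gamma,
                  int start, double slack, double rho, double tol,
                  int max_iter, bool adapt_rho, double rho_max) {
  const arma::uword n = Ys.n_rows, T = Ys.n_cols;
  arma::mat Yc = Ys + slack;
  arma::mat Gamma(n, T, arma::fill::zeros);
  arma::rowvec lambda(T, arma::fill::zeros);
  arma::rowvec q = v;
  arma::mat UV = u * v;
  arma::mat R = arma::max(Yc - UV, arma::mat(n, T, arma::fill::zeros));
  const double yfro = arma::norm(Ys, "fro");
  bool converged = false;
  int it = 0;
  arma::rowvec z(T), qbuf(T);
  while (true) {
    ++it;
    arma::mat M = Yc - R + Gamma / rho;
    if (update_u) {
      arma::vec u_new = M * v.t();
      u_new.transform([](double x) { return x > 0.0 ? x : 0.0; });
      double nu = arma::norm(u_new, 2);
      if (nu > 0.0) u = u_new / nu;
    }
    arma::rowvec num = u.t() * (Gamma + rho * (Yc - R));
    num += lambda + rho * q;
    v = num / (rho * (arma::dot(u, u) + 1.0));
    v.transform([](double x) { return x > 0.0 ? x : 0.0; });
    z = v - lambda / rho;
    if (has_constraint) {
      int s = start - 1;           // 0-based index of first constrained entry
      if (s < 0) s = 0;
      for (int j = 0; j < s; ++j) q[j] = z[j];
      if (s < (int)T)
        pava_gamma_decreasing_core(z.memptr() + s, (int)T - s, gamma,
                                   q.memptr() + s);
    } else {
      q = z;
    }
    lambda += rho * (q - v);
    arma::mat UV_new = u * v;
    arma::mat L = Yc - UV_new;
    R = (rho * L + Gamma + slack) / (1.0 + rho);
    R.transform([](double x) { return x > 0.0 ? x : 0.0; });
    Gamma += rho * (L - R);

    double d_uv = arma::norm(UV_new - UV, "fro") / yfro;
    double r_split = arma::norm(L - R, "fro") / yfro;
    double r_cons = arma::norm(q - v, 2) / (arma::norm(v, 2) + 1e-12);
    double overshoot = (UV_new - Yc).max();
    UV = UV_new;
    if (d_uv < tol && r_split < tol && r_cons < tol && overshoot < 10 * tol) {
      converged = true;
      break;
    }
    // stalled: iterates and residuals settled but the feasibility overshoot
    // is pinned with the penalty already at its ceiling -- no further
    // progress is possible, return the best iterate
    if (d_uv < tol && r_split < tol && r_cons < tol && rho >= rho_max) break;
    if (it >= max_iter) break;
    if (adapt_rho && it % 25 == 0 && overshoot > 10 * tol && rho < rho_max)
      rho *= 2.0;
  }
  return List::create(_["u"] = u, _["v"] = v, _["q"] = q, _["R_res"] = R,
                      _["Gamma"] = Gamma, _["lambda"] = lambda,
                      _["converged"] = converged, _["n_iter"] = it);
}
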
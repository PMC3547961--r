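// Profiled marginal likelihood pieces for the Gaussian linear mixed model.
//
// Per-subject covariance is V_j = sigma^2 * (Z_j Gstar Z_j' + C_j(phi)),
// with Gstar = G / sigma^2 and C_j either the identity or the CAR(1)
// correlation phi^|age_s - age_t|.  Fixed effects and sigma^2 are profiled
// out by generalized least squares, so the optimizer only searches the
// scaled covariance parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat car1_mat(const arma::vec& ages, double phi) {
  const arma::uword n = ages.n_elem;
  arma::mat C(n, n);
  for (arma::uword s = 0; s < n; ++s)
    for (arma::uword t = 0; t <= s; ++t) {
      double v = (phi == 0.0 && s != t) ? 0.0
                                        : std::pow(phi, std::abs(ages[s] - ages[t]));
      C(s, t) = v;
      C(t, s) = v;
    }
  return C;
}

// [[Rcpp::export]]
List lmm_profile_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                     const arma::ivec& sub_start, const arma::ivec& sub_len,
                     const arma::vec& ages, const arma::mat& Gstar,
                     double phi, bool car1) {
  const arma::uword p = X.n_cols;
  const arma::uword nsub = sub_start.n_elem;
  arma::mat XtX(p, p, arma::fill::zeros);
  arma::vec Xty(p, arma::fill::zeros);
  double yty = 0.0, ldet = 0.0;
  bool ok = true;

  for (arma::uword j = 0; j < nsub && ok; ++j) {
    const arma::uword a = sub_start[j];
    const arma::uword n = sub_len[j];
    arma::mat Zj = Z.rows(a, a + n - 1);
    arma::mat Vj = Zj * Gstar * Zj.t();
    if (car1) {
      Vj += car1_mat(ages.subvec(a, a + n - 1), phi);
    } else {
      Vj.diag() += 1.0;
    }
    Vj = 0.5 * (Vj + Vj.t());
    arma::mat L;
    if (!arma::chol(L, Vj, "lower")) { ok = false; break; }
    ldet += 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat Xs = arma::solve(arma::trimatl(L), X.rows(a, a + n - 1));
    arma::vec ys = arma::solve(arma::trimatl(L), y.subvec(a, a + n - 1));
    XtX += Xs.t() * Xs;
    Xty += Xs.t() * ys;
    yty += arma::dot(ys, ys);
  }
  return List::create(_["ok"] = ok, _["ldet"] = ldet, _["XtX"] = XtX,
                      _["Xty"] = Xty, _["yty"] = yty);
}

// Random-effect predictions (BLUPs) and subject-level fitted values at given
// parameters: b_j = Gstar Z_j' Vstar_j^{-1} (y_j - X_j beta).
// [[Rcpp::export]]
List lmm_ranef_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                   const arma::ivec& sub_start, const arma::ivec& sub_len,
                   const arma::vec& ages, const arma::mat& Gstar,
                   double phi, bool car1, const arma::vec& beta) {
  const arma::uword nsub = sub_start.n_elem;
  const arma::uword q = Z.n_cols;
  arma::mat b(nsub, q, arma::fill::zeros);
  arma::vec fitted = X * beta;
  arma::vec resid_marg = y - fitted;
  for (arma::uword j = 0; j < nsub; ++j) {
    const arma::uword a = sub_start[j];
    const arma::uword n = sub_len[j];
    arma::mat Zj = Z.rows(a, a + n - 1);
    arma::mat Vj = Zj * Gstar * Zj.t();
    if (car1) {
      Vj += car1_mat(ages.subvec(a, a + n - 1), phi);
    } else {
      Vj.diag() += 1.0;
    }
    Vj = 0.5 * (Vj + Vj.t());
    arma::vec rj = resid_marg.subvec(a, a + n - 1);
    arma::vec bj = Gstar * Zj.t() * arma::solve(Vj, rj,
                                                arma::solve_opts::likely_sympd);
    b.row(j) = bj.t();
    fitted.subvec(a, a + n - 1) += Zj * bj;
  }
  return List::create(_["ranef"] = b, _["fitted_subject"] = fitted);
}
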
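// E-step of the skew-t linear mixed model EM, per subject, in closed form.
// Mirrors the moment derivation used by the R reference implementation in
// R/skew-t-lmm.R (validated against 2-D quadrature in the tests); written
// in C++ because it is evaluated once per subject per EM iteration.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List stlmm_estep_cpp(const arma::vec& y, const arma::mat& X,
                     const arma::mat& Z, const arma::ivec& sub_start,
                     const arma::ivec& sub_len, const arma::vec& beta,
                     double sigma2, const arma::vec& Delta,
                     const arma::mat& Gamma, double nu, double cnu,
                     bool logf_only) {
  const arma::uword nsub = sub_start.n_elem;
  const arma::uword q = Delta.n_elem;
  const arma::uword p = X.n_cols;
  double logf_sum = 0.0;
  arma::vec EU(nsub), EUt(nsub), EUt2(nsub), logf(nsub);
  arma::mat EUb(nsub, q), EUtb(nsub, q), Eb(nsub, q), EUbb(nsub, q * q);
  arma::mat XtWX(p, p, arma::fill::zeros);
  arma::vec XtWr(p, arma::fill::zeros);
  arma::mat Gamma_inv = arma::inv_sympd(arma::symmatu(Gamma));
  const double lg_nu2 = std::lgamma(nu / 2.0);

  for (arma::uword j = 0; j < nsub; ++j) {
    const arma::uword a = sub_start[j];
    const arma::uword n = sub_len[j];
    arma::mat Zj = Z.rows(a, a + n - 1);
    arma::mat Xj = X.rows(a, a + n - 1);
    arma::vec yj = y.subvec(a, a + n - 1);
    arma::vec Zd = Zj * Delta;
    arma::vec resid = yj - Xj * beta;
    arma::vec r = resid + cnu * Zd;
    arma::mat Psi = Zj * Gamma * Zj.t();
    Psi.diag() += sigma2;
    Psi = arma::symmatu(Psi);
    arma::mat Psi_chol = arma::chol(Psi, "lower");
    arma::vec Pr = arma::solve(arma::trimatl(Psi_chol), r);
    Pr = arma::solve(arma::trimatu(Psi_chol.t()), Pr);
    arma::vec Pzd = arma::solve(arma::trimatl(Psi_chol), Zd);
    Pzd = arma::solve(arma::trimatu(Psi_chol.t()), Pzd);
    double M2 = 1.0 / (1.0 + arma::dot(Zd, Pzd));
    double M = std::sqrt(M2);
    double zr = arma::dot(Zd, Pr);
    double muT = M2 * zr;
    double d = arma::dot(r, Pr) - M2 * zr * zr;
    double ldet_Sigma = 2.0 * arma::accu(arma::log(Psi_chol.diag())) -
      std::log(M2);
    double A = muT / M;
    double a0 = (nu + n) / 2.0;
    double b0 = (nu + d) / 2.0;
    double TA = R::pt(A * std::sqrt(a0 / b0), 2.0 * a0, 1, 0);
    double lf = std::log(2.0) + std::lgamma(a0) - lg_nu2 -
      (n / 2.0) * std::log(M_PI * nu) - 0.5 * ldet_Sigma -
      a0 * std::log1p(d / nu) + std::log(TA);
    logf[j] = lf;
    logf_sum += lf;
    if (logf_only) continue;

    // I(k) and J(k) moment ratios
    double I1 = std::exp(std::lgamma(a0 + 1.0) - std::lgamma(a0)) / b0 *
      R::pt(A * std::sqrt((a0 + 1.0) / b0), 2.0 * (a0 + 1.0), 1, 0) / TA;
    double Jhalf = std::exp(std::lgamma(a0 + 0.5) - std::lgamma(a0) +
                            a0 * std::log(b0) -
                            (a0 + 0.5) * std::log(b0 + A * A / 2.0)) /
      (std::sqrt(2.0 * M_PI) * TA);
    double Jmhalf = std::exp(std::lgamma(a0 - 0.5) - std::lgamma(a0) +
                             a0 * std::log(b0) -
                             (a0 - 0.5) * std::log(b0 + A * A / 2.0)) /
      (std::sqrt(2.0 * M_PI) * TA);
    double eu = I1;
    double eut = muT * eu + M * Jhalf;
    double eut2 = muT * muT * eu + M2 + muT * M * Jhalf;
    double et = muT + M * Jmhalf;
    // conditional law of b given (y, T, U)
    arma::mat Lambda = arma::inv_sympd(arma::symmatu(Gamma_inv +
                                                     Zj.t() * Zj / sigma2));
    arma::vec s = Lambda * (Zj.t() * resid) / sigma2;
    arma::vec S = Lambda * (Gamma_inv * Delta);
    double eutc = eut - cnu * eu;
    double eut2c = eut2 - 2.0 * cnu * eut + cnu * cnu * eu;
    arma::vec eub = s * eu + S * eutc;
    arma::mat eubb = Lambda + s * s.t() * eu +
      (s * S.t() + S * s.t()) * eutc + S * S.t() * eut2c;
    arma::vec eutb = s * eutc + S * eut2c;
    EU[j] = eu; EUt[j] = eutc; EUt2[j] = eut2c;
    EUb.row(j) = eub.t();
    EUtb.row(j) = eutb.t();
    Eb.row(j) = (s + S * (et - cnu)).t();
    EUbb.row(j) = arma::vectorise(eubb).t();
    XtWX += eu * (Xj.t() * Xj);
    XtWr += Xj.t() * (eu * yj - Zj * eub);
  }
  if (logf_only) return List::create(_["logf_sum"] = logf_sum);
  return List::create(_["logf_sum"] = logf_sum, _["logf"] = logf,
                      _["EU"] = EU, _["EUt"] = EUt, _["EUt2"] = EUt2,
                      _["EUb"] = EUb, _["EUtb"] = EUtb, _["EUbb"] = EUbb,
                      _["Eb"] = Eb, _["XtWX"] = XtWX, _["XtWr"] = XtWr);
}

// rss and Gamma sufficient statistics at the updated beta / Delta.
// [[Rcpp::export]]
List stlmm_mstep_cpp(const arma::vec& y, const arma::mat& X,
                     const arma::mat& Z, const arma::ivec& sub_start,
                     const arma::ivec& sub_len, const arma::vec& beta_new,
                     const arma::vec& EU, const arma::mat& EUb,
                     const arma::mat& EUbb, const arma::vec& EUt2,
                     const arma::mat& EUtb, const arma::vec& Delta_new) {
  const arma::uword nsub = sub_start.n_elem;
  const arma::uword q = EUb.n_cols;
  double rss = 0.0;
  arma::mat SGam(q, q, arma::fill::zeros);
  for (arma::uword j = 0; j < nsub; ++j) {
    const arma::uword a = sub_start[j];
    const arma::uword n = sub_len[j];
    arma::mat Zj = Z.rows(a, a + n - 1);
    arma::vec ry = y.subvec(a, a + n - 1) -
      X.rows(a, a + n - 1) * beta_new;
    arma::mat Bj = arma::reshape(EUbb.row(j).t(), q, q);
    rss += EU[j] * arma::dot(ry, ry) -
      2.0 * arma::dot(ry, Zj * EUb.row(j).t()) +
      arma::trace(Zj.t() * Zj * Bj);
    arma::vec tb = EUtb.row(j).t();
    SGam += Bj - tb * Delta_new.t() - Delta_new * tb.t() +
      Delta_new * Delta_new.t() * EUt2[j];
  }
  return List::create(_["rss"] = rss, _["SGam"] = SGam);
}
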
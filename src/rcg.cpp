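// Numerically stable kernels for the ratio-of-correlated-gammas density
// and its derivatives. The discriminant
//   D = ((theta-1)b + 1)^2 - 4 rho theta b(1-b)
// is evaluated in the factored form (t - 2r)(t + 2r),
// r = sqrt(rho theta b(1-b)), with
//   t - 2r = (sqrt(theta b) - sqrt(1-b))^2 + 2(1-sqrt(rho)) sqrt(theta b(1-b))
// so that no catastrophic cancellation occurs as rho -> 1, theta b -> 1-b.

#include <Rcpp.h>
using namespace Rcpp;

static inline void rcg_pieces(double b, double theta, double rho,
                              double &s, double &t, double &D,
                              double &logD) {
  s = b * (1.0 - b);
  t = (theta - 1.0) * b + 1.0;
  double rt = std::sqrt(theta * s);
  double sqrho = std::sqrt(rho);
  double one_m_sqrho = (1.0 - rho) / (1.0 + sqrho);
  double d1 = std::sqrt(theta * b) - std::sqrt(1.0 - b);
  double lo = d1 * d1 + 2.0 * one_m_sqrho * rt;
  double hi = t + 2.0 * sqrho * rt;
  D = lo * hi;
  logD = std::log(lo) + std::log(hi);
}

// [[Rcpp::export(name = ".cpp_rcg_logpdf")]]
NumericVector cpp_rcg_logpdf(NumericVector b, double alpha, double rho,
                             NumericVector theta) {
  R_xlen_t n = b.size();
  NumericVector out(n);
  double cst = R::lgammafn(2.0 * alpha) - 2.0 * R::lgammafn(alpha) +
    alpha * std::log1p(-rho);
  bool th_scalar = theta.size() == 1;
  for (R_xlen_t i = 0; i < n; i++) {
    double th = th_scalar ? theta[0] : theta[i];
    double s, t, D, logD;
    rcg_pieces(b[i], th, rho, s, t, D, logD);
    out[i] = cst + alpha * std::log(th) + (alpha - 1.0) * std::log(s) +
      std::log(t) - (alpha + 0.5) * logD;
  }
  return out;
}

// Per-observation first and second derivatives on the linear-predictor
// scale plus summed partials for alpha and rho; also returns the total
// log-likelihood so a fused evaluate-and-differentiate call is cheap.
// [[Rcpp::export(name = ".cpp_rcg_parts")]]
List cpp_rcg_parts(NumericVector b, NumericVector eta, double alpha,
                   double rho) {
  R_xlen_t n = b.size();
  NumericVector dl_deta(n), d2l_deta2(n);
  double sum_da = 0.0, sum_dr = 0.0, ll = 0.0;
  double cst = R::lgammafn(2.0 * alpha) - 2.0 * R::lgammafn(alpha) +
    alpha * std::log1p(-rho);
  double dig = 2.0 * R::digamma(2.0 * alpha) - 2.0 * R::digamma(alpha) +
    std::log1p(-rho);
  for (R_xlen_t i = 0; i < n; i++) {
    double e = eta[i];
    if (e > 500.0) e = 500.0;
    if (e < -500.0) e = -500.0;
    double th = std::exp(e);
    double s, t, D, logD;
    rcg_pieces(b[i], th, rho, s, t, D, logD);
    double bt = b[i] * th;
    double A = bt / t;
    double Dp = 2.0 * t * bt - 4.0 * rho * th * s;
    double Dpp = 2.0 * bt * bt + 2.0 * t * bt - 4.0 * rho * th * s;
    double B = Dp / D;
    dl_deta[i] = alpha + A - (alpha + 0.5) * B;
    d2l_deta2[i] = (A - A * A) - (alpha + 0.5) * (Dpp / D - B * B);
    sum_da += dig + e + std::log(s) - logD;
    sum_dr += -alpha / (1.0 - rho) + (alpha + 0.5) * 4.0 * th * s / D;
    ll += cst + alpha * e + (alpha - 1.0) * std::log(s) + std::log(t) -
      (alpha + 0.5) * logD;
  }
  return List::create(_["dl_deta"] = dl_deta,
                      _["d2l_deta2"] = d2l_deta2,
                      _["dl_dalpha"] = sum_da,
                      _["dl_drho"] = sum_dr,
                      _["loglik"] = ll);
}
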
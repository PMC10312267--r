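// Spectral forward model for the effective-connectivity DCM.
//
// Parameter vector layout (length p*(p-1) + p + p + 4):
//   [ A off-diagonals row-major (i fixed, j varying, j != i),
//     self log-scaling values,
//     driving weights C,
//     log-amplitude neural, log-exponent neural,
//     log-amplitude observation, log-exponent observation ]
//
// Predicted cross-spectrum at frequency f (Hz):
//   G_y(f) = K(f) G_v(f) K(f)^H + G_e(f)
//   K(f)   = h(f) (2*pi*i*f I - A_eff)^{-1}
//   G_v(f) = av0 exp(a_v) f^{-bv0 exp(b_v)} I + upow(f) C C'
//   G_e(f) = ae0 exp(a_e) f^{-be0 exp(b_e)} I
// with A_eff(i,i) = -0.5 exp(s_i). Data vector: per frequency, the real
// parts of the upper triangle (incl. diagonal, column-major) then the
// imaginary parts of the strict upper triangle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct DcmPars {
  mat A;
  vec C;
  double gv_amp, gv_exp, ge_amp, ge_exp;
};

static DcmPars unpack(const vec& theta, int p,
                      double av0, double bv0, double ae0, double be0) {
  DcmPars P;
  P.A.set_size(p, p);
  int idx = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (j != i) P.A(i, j) = theta(idx++);
  for (int i = 0; i < p; ++i) P.A(i, i) = -0.5 * std::exp(theta(idx++));
  P.C.set_size(p);
  for (int i = 0; i < p; ++i) P.C(i) = theta(idx++);
  P.gv_amp = av0 * std::exp(theta(idx++));
  P.gv_exp = bv0 * std::exp(theta(idx++));
  P.ge_amp = ae0 * std::exp(theta(idx++));
  P.ge_exp = be0 * std::exp(theta(idx++));
  return P;
}

static cx_mat predict_freq(const DcmPars& P, double f, cx_double h, double up) {
  int p = P.A.n_rows;
  cx_mat M = cx_double(0.0, 2.0 * datum::pi * f) * cx_mat(eye(p, p), mat(p, p, fill::zeros))
             - cx_mat(P.A, mat(p, p, fill::zeros));
  cx_mat Minv;
  if (!inv(Minv, M)) {
    Rcpp::stop("singular transfer matrix at frequency %f Hz", f);
  }
  cx_mat K = h * Minv;
  mat Gv = P.gv_amp * std::pow(f, -P.gv_exp) * eye(p, p);
  if (up != 0.0) Gv += up * (P.C * P.C.t());
  cx_mat Gy = K * cx_mat(Gv, mat(p, p, fill::zeros)) * K.t();  // .t() = ctrans
  double ge = P.ge_amp * std::pow(f, -P.ge_exp);
  Gy.diag() += cx_double(ge, 0.0);
  return Gy;
}

static vec stack_all(const vec& theta, int p, const vec& freq,
                     const cx_vec& h, const vec& upow,
                     double av0, double bv0, double ae0, double be0) {
  DcmPars P = unpack(theta, p, av0, bv0, ae0, be0);
  int nf = freq.n_elem;
  int nre = p * (p + 1) / 2, nim = p * (p - 1) / 2;
  vec out(nf * (nre + nim));
  int idx = 0;
  for (int k = 0; k < nf; ++k) {
    cx_mat G = predict_freq(P, freq(k), h(k), upow(k));
    for (int j = 0; j < p; ++j)
      for (int i = 0; i <= j; ++i) out(idx++) = G(i, j).real();
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < j; ++i) out(idx++) = G(i, j).imag();
  }
  return out;
}

// [[Rcpp::export]]
arma::vec csd_predict_stack_cpp(const arma::vec& theta, int p,
                                const arma::vec& freq, const arma::cx_vec& h,
                                const arma::vec& upow, double av0, double bv0,
                                double ae0, double be0) {
  return stack_all(theta, p, freq, h, upow, av0, bv0, ae0, be0);
}

// [[Rcpp::export]]
arma::cx_cube csd_predict_cube_cpp(const arma::vec& theta, int p,
                                   const arma::vec& freq, const arma::cx_vec& h,
                                   const arma::vec& upow, double av0, double bv0,
                                   double ae0, double be0) {
  DcmPars P = unpack(theta, p, av0, bv0, ae0, be0);
  cx_cube out(p, p, freq.n_elem);
  for (uword k = 0; k < freq.n_elem; ++k) {
    out.slice(k) = predict_freq(P, freq(k), h(k), upow(k));
  }
  return out;
}

// central-difference Jacobian of the stacked prediction w.r.t. theta
// [[Rcpp::export]]
arma::mat csd_jacobian_cpp(const arma::vec& theta, int p,
                           const arma::vec& freq, const arma::cx_vec& h,
                           const arma::vec& upow, double av0, double bv0,
                           double ae0, double be0, double step = 1e-4) {
  int np = theta.n_elem;
  vec base = stack_all(theta, p, freq, h, upow, av0, bv0, ae0, be0);
  mat J(base.n_elem, np);
  for (int m = 0; m < np; ++m) {
    vec tp = theta, tm = theta;
    tp(m) += step;
    tm(m) -= step;
    J.col(m) = (stack_all(tp, p, freq, h, upow, av0, bv0, ae0, be0)
                - stack_all(tm, p, freq, h, upow, av0, bv0, ae0, be0)) / (2.0 * step);
  }
  return J;
}
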
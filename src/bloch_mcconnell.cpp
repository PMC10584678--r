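// Two-site Bloch-McConnell propagation kernels.
//
// State labelling follows the kinetic convention used throughout the
// package: state 2 is the ground state (population p2 = 1 - p1), state 1
// the excited state (population p1).  k21 is the 2 -> 1 rate, k12 the
// 1 -> 2 rate, k_ex = k21 + k12 and p1 = k21 / k_ex.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Closed-form matrix exponential of a complex 2x2 matrix.
static cx_mat22 expm2(const cx_mat22 &A) {
  cx_double tr2 = (A(0, 0) + A(1, 1)) / 2.0;
  cx_double q = std::sqrt((A(0, 0) - A(1, 1)) * (A(0, 0) - A(1, 1)) / 4.0 +
                          A(0, 1) * A(1, 0));
  cx_mat22 B = A;
  B(0, 0) -= tr2;
  B(1, 1) -= tr2;
  cx_double f = (std::abs(q) < 1e-14) ? cx_double(1.0, 0.0)
                                      : std::sinh(q) / q;
  cx_mat22 E;
  E.eye();
  E = std::cosh(q) * E + f * B;
  return std::exp(tr2) * E;
}

// CPMG R2,eff profile for in-phase single-spin magnetization.
//
// dw_rad : excited-minus-ground shift difference, rad/s
// r2g/r2e: intrinsic transverse rates of ground/excited state, 1/s
// kex,p1 : global exchange parameters
// t_relax: constant relaxation delay, s
// nu     : CPMG frequencies, Hz (nu * t_relax must be integer cycles)
// dominant: if true, return the decay rate of the slowest eigenmode of the
//           cycle propagator (the quantity the Carver-Richards closed form
//           describes); otherwise the end-point amplitude definition
//           -ln(I/I0)/T with ground-state detection.
// [[Rcpp::export]]
arma::vec cpmg_r2eff_cpp(double dw_rad, double r2g, double r2e, double kex,
                         double p1, double t_relax, const arma::vec &nu,
                         bool dominant) {
  const double p2 = 1.0 - p1;
  const double k21 = p1 * kex;  // ground -> excited
  const double k12 = p2 * kex;  // excited -> ground
  cx_mat22 A;
  A(0, 0) = cx_double(-r2g - k21, 0.0);
  A(0, 1) = cx_double(k12, 0.0);
  A(1, 0) = cx_double(k21, 0.0);
  A(1, 1) = cx_double(-r2e - k12, dw_rad);

  vec out(nu.n_elem);
  for (uword i = 0; i < nu.n_elem; ++i) {
    const double v = nu(i);
    const double ncyc_d = v * t_relax;
    const int ncyc = (int)std::lround(ncyc_d);
    const double tau = 1.0 / (4.0 * v);
    cx_mat22 E = expm2(tau * A);
    if (dominant) {
      // one cycle: (tau-180-tau)(tau-180-tau) == E conj(E) conj(E) E
      cx_mat22 U = E * conj(E) * conj(E) * E;
      cx_double tr2 = (U(0, 0) + U(1, 1)) / 2.0;
      cx_double q = std::sqrt(tr2 * tr2 - (U(0, 0) * U(1, 1) - U(0, 1) * U(1, 0)));
      double lam = std::max(std::abs(tr2 + q), std::abs(tr2 - q));
      out(i) = -v * std::log(lam);
    } else {
      cx_vec2 M;
      M(0) = cx_double(p2, 0.0);
      M(1) = cx_double(p1, 0.0);
      for (int c = 0; c < 2 * ncyc; ++c) {
        M = E * conj(E * M);  // one (tau-180-tau) echo element
      }
      out(i) = -std::log(std::real(M(0)) / p2) / t_relax;
    }
  }
  return out;
}

// CEST profile: z-magnetization of the ground state after irradiation for
// t_ex at field w1 (rad/s), normalized by its equilibrium value.
//
// dg, de : offset from resonance of ground / excited state for each
//          irradiation position, rad/s (Omega_state - omega_rf)
// [[Rcpp::export]]
arma::vec cest_profile_cpp(const arma::vec &dg, const arma::vec &de,
                           double r1g, double r2g, double r1e, double r2e,
                           double kex, double p1, double t_ex, double w1_rad) {
  const double p2 = 1.0 - p1;
  const double k21 = p1 * kex;
  const double k12 = p2 * kex;

  vec out(dg.n_elem);
  if (t_ex == 0.0) {
    out.ones();
    return out;
  }
  // 7x7 homogeneous form: (x2,y2,z2, x1,y1,z1, 1)
  mat A(7, 7, fill::zeros);
  A(0, 0) = -r2g - k21; A(0, 3) = k12;
  A(1, 1) = -r2g - k21; A(1, 4) = k12;
  A(2, 2) = -r1g - k21; A(2, 5) = k12;
  A(3, 3) = -r2e - k12; A(3, 0) = k21;
  A(4, 4) = -r2e - k12; A(4, 1) = k21;
  A(5, 5) = -r1e - k12; A(5, 2) = k21;
  A(1, 2) = -w1_rad;    A(2, 1) = w1_rad;   // B1 along x
  A(4, 5) = -w1_rad;    A(5, 4) = w1_rad;
  A(2, 6) = r1g * p2;   A(5, 6) = r1e * p1; // recovery to equilibrium

  vec M0(7, fill::zeros);
  M0(2) = p2;
  M0(5) = p1;
  M0(6) = 1.0;

  for (uword i = 0; i < dg.n_elem; ++i) {
    A(0, 1) = -dg(i); A(1, 0) = dg(i);
    A(3, 4) = -de(i); A(4, 3) = de(i);
    mat P = expmat(t_ex * A);
    vec M = P * M0;
    out(i) = M(2) / p2;
  }
  return out;
}
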
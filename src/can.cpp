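// Forward-Euler integration of the stripe-cell continuous attractor network:
//   tau * ds/dt + s = f( W s + B ),   f(x) = max(x, 0)
//   B_i = 1 + alpha * e_i * proj + inject_i
// where proj is the scalar projection of the agent's velocity onto the
// plate's preferred direction and inject is an optional additive input
// (boundary-cell corrective drive).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void euler_substeps(const arma::mat& W, arma::vec& s,
                                  const arma::vec& e, double alpha,
                                  double proj, const arma::vec& inject,
                                  double dt, double tau, int nsub) {
  const double r = dt / tau;
  const arma::uword n = s.n_elem;
  arma::vec B = 1.0 + alpha * proj * e + inject;
  arma::vec u(n);
  // explicit column accumulation: predictable single-threaded speed for the
  // small dense matrices used here (BLAS gemv threading thrashes)
  for (int k = 0; k < nsub; ++k) {
    u = B;
    const double* w = W.memptr();
    for (arma::uword j = 0; j < n; ++j) {
      const double sj = s(j);
      if (sj != 0.0) {
        const double* wj = w + j * n;
        double* up = u.memptr();
        for (arma::uword i = 0; i < n; ++i) up[i] += wj[i] * sj;
      }
    }
    u.transform([](double x) { return x > 0.0 ? x : 0.0; });
    s += r * (u - s);
    // flush vanishing rates to exact zero: silent cells otherwise decay
    // into subnormal doubles, which are pathologically slow and never
    // trigger the zero-skip above
    s.transform([](double x) { return x > 1e-12 ? x : 0.0; });
  }
}

// One sampling interval of nsub Euler substeps; returns the updated state.
// [[Rcpp::export]]
arma::vec can_step_cpp(const arma::mat& W, const arma::vec& s,
                       const arma::vec& e, double alpha, double proj,
                       const arma::vec& inject, double dt, double tau,
                       int nsub) {
  arma::vec out = s;
  euler_substeps(W, out, e, alpha, proj, inject, dt, tau, nsub);
  return out;
}

// Integrate a whole projection sequence; column t of the result is the state
// after sample t's substeps (no boundary injection).
// [[Rcpp::export]]
arma::mat can_run_cpp(const arma::mat& W, const arma::vec& s0,
                      const arma::vec& e, double alpha,
                      const arma::vec& proj, double dt, double tau,
                      int nsub) {
  const arma::uword n = s0.n_elem, T = proj.n_elem;
  arma::mat out(n, T);
  arma::vec s = s0;
  arma::vec inject(n, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    euler_substeps(W, s, e, alpha, proj(t), inject, dt, tau, nsub);
    out.col(t) = s;
  }
  return out;
}
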
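// Binary-state speciation-extinction (BiSSE) likelihood.
//
// Along each branch, four coupled ODEs are integrated rootward in time t
// (t = 0 at the branch's young end):
//   E_i' = mu_i - (lambda_i + mu_i + q_ij) E_i + lambda_i E_i^2 + q_ij E_j
//   D_i' = -(lambda_i + mu_i + q_ij) D_i + 2 lambda_i E_i D_i + q_ij D_j
// E_i = P(a lineage in state i leaves no sampled descendants), D_i = density
// of the observed subtree given state i at the branch's old end.  Tips start
// at D_i = f_i [state == i] (both f_i when missing), E_i = 1 - f_i.  At an
// internal node D_i = D_left,i * D_right,i * lambda_i.  D is renormalized
// per branch with a log accumulator to avoid underflow.
//
// Integrator: adaptive Cash-Karp RK4(5) with absolute/relative tolerance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct BissePars {
  double la0, la1, mu0, mu1, q01, q10;
};

static inline void deriv(const BissePars& p, const double* y, double* dy) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = p.mu0 - (p.la0 + p.mu0 + p.q01) * E0 + p.la0 * E0 * E0 + p.q01 * E1;
  dy[1] = p.mu1 - (p.la1 + p.mu1 + p.q10) * E1 + p.la1 * E1 * E1 + p.q10 * E0;
  dy[2] = -(p.la0 + p.mu0 + p.q01) * D0 + 2.0 * p.la0 * E0 * D0 + p.q01 * D1;
  dy[3] = -(p.la1 + p.mu1 + p.q10) * D1 + 2.0 * p.la1 * E1 * D1 + p.q10 * D0;
}

// Cash-Karp tableau
static const double CK_B21 = 1.0 / 5.0;
static const double CK_B31 = 3.0 / 40.0, CK_B32 = 9.0 / 40.0;
static const double CK_B41 = 3.0 / 10.0, CK_B42 = -9.0 / 10.0, CK_B43 = 6.0 / 5.0;
static const double CK_B51 = -11.0 / 54.0, CK_B52 = 5.0 / 2.0,
                    CK_B53 = -70.0 / 27.0, CK_B54 = 35.0 / 27.0;
static const double CK_B61 = 1631.0 / 55296.0, CK_B62 = 175.0 / 512.0,
                    CK_B63 = 575.0 / 13824.0, CK_B64 = 44275.0 / 110592.0,
                    CK_B65 = 253.0 / 4096.0;
static const double CK_C1 = 37.0 / 378.0, CK_C3 = 250.0 / 621.0,
                    CK_C4 = 125.0 / 594.0, CK_C6 = 512.0 / 1771.0;
static const double CK_D1 = CK_C1 - 2825.0 / 27648.0,
                    CK_D3 = CK_C3 - 18575.0 / 48384.0,
                    CK_D4 = CK_C4 - 13525.0 / 55296.0,
                    CK_D5 = -277.0 / 14336.0,
                    CK_D6 = CK_C6 - 1.0 / 4.0;

// one adaptive-step integration over [0, len]; returns false on failure
static bool integrate_branch(const BissePars& p, double* y, double len,
                             double rtol, double atol) {
  if (len <= 0) return true;
  double t = 0.0;
  double h = len / 10.0;
  const double hmin = len * 1e-12;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], ytmp[4], yerr[4], ynew[4];
  int iter = 0;
  while (t < len) {
    if (++iter > 100000) return false;
    if (t + h > len) h = len - t;
    deriv(p, y, k1);
    for (int i = 0; i < 4; ++i) ytmp[i] = y[i] + h * CK_B21 * k1[i];
    deriv(p, ytmp, k2);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (CK_B31 * k1[i] + CK_B32 * k2[i]);
    deriv(p, ytmp, k3);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (CK_B41 * k1[i] + CK_B42 * k2[i] + CK_B43 * k3[i]);
    deriv(p, ytmp, k4);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (CK_B51 * k1[i] + CK_B52 * k2[i] + CK_B53 * k3[i] +
                            CK_B54 * k4[i]);
    deriv(p, ytmp, k5);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (CK_B61 * k1[i] + CK_B62 * k2[i] + CK_B63 * k3[i] +
                            CK_B64 * k4[i] + CK_B65 * k5[i]);
    deriv(p, ytmp, k6);
    double err = 0.0;
    for (int i = 0; i < 4; ++i) {
      ynew[i] = y[i] + h * (CK_C1 * k1[i] + CK_C3 * k3[i] + CK_C4 * k4[i] +
                            CK_C6 * k6[i]);
      yerr[i] = h * (CK_D1 * k1[i] + CK_D3 * k3[i] + CK_D4 * k4[i] +
                     CK_D5 * k5[i] + CK_D6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > err) err = e;
    }
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = ynew[i];
      // keep the state physical
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0) y[i] = 0;
        if (y[i] > 1) y[i] = 1;
      }
      for (int i = 2; i < 4; ++i) if (y[i] < 0) y[i] = 0;
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(err, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) return false;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".bisse_lnl_cpp")]]
List bisse_lnl_cpp(IntegerMatrix edge, NumericVector edge_length, int n_tip,
                   IntegerVector tip_state, NumericVector pars,
                   NumericVector sampling_f, int root_mode,
                   NumericVector root_p, bool condition_surv, double rtol) {
  BissePars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  const int n_node = n_tip + (int)(edge.nrow() / 2) + 1;  // binary rooted
  const int n_total = 2 * n_tip - 1;
  std::vector<double> E0(n_total + 1), E1(n_total + 1),
      D0(n_total + 1), D1(n_total + 1);
  std::vector<int> seen(n_total + 1, 0);
  (void)n_node;
  double logcomp = 0.0;
  int n_clamped = 0;
  const double f0 = sampling_f[0], f1 = sampling_f[1];
  // tip initial conditions
  for (int i = 1; i <= n_tip; ++i) {
    E0[i] = 1.0 - f0;
    E1[i] = 1.0 - f1;
    int s = tip_state[i - 1];
    if (s == 0) { D0[i] = f0; D1[i] = 0.0; }
    else if (s == 1) { D0[i] = 0.0; D1[i] = f1; }
    else { D0[i] = f0; D1[i] = f1; }  // missing state
  }
  // edges must arrive in postorder (children before parents)
  const double atol = rtol * 1e-3;
  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    double y[4] = {E0[ch], E1[ch], D0[ch], D1[ch]};
    bool ok = integrate_branch(p, y, edge_length[e], rtol, atol);
    if (!ok) {
      ok = integrate_branch(p, y, edge_length[e], rtol * 1e-2, atol * 1e-2);
      if (!ok)
        return List::create(_["lnl"] = R_NegInf, _["failed"] = true,
                            _["n_clamped"] = n_clamped);
    }
    if (y[2] < 0) { y[2] = 0; ++n_clamped; }
    if (y[3] < 0) { y[3] = 0; ++n_clamped; }
    double s = y[2] + y[3];
    if (s > 0) { y[2] /= s; y[3] /= s; logcomp += std::log(s); }
    if (!seen[par]) {
      E0[par] = y[0]; E1[par] = y[1];
      D0[par] = y[2]; D1[par] = y[3];
      seen[par] = 1;
    } else {
      // combine the two daughters at the node
      E0[par] = 0.5 * (E0[par] + y[0]);
      E1[par] = 0.5 * (E1[par] + y[1]);
      D0[par] = D0[par] * y[2] * p.la0;
      D1[par] = D1[par] * y[3] * p.la1;
      seen[par] = 2;
    }
  }
  int root = n_tip + 1;
  double d0 = D0[root], d1 = D1[root];
  double e0 = E0[root], e1 = E1[root];
  if (condition_surv) {
    double s0 = p.la0 * (1.0 - e0) * (1.0 - e0);
    double s1 = p.la1 * (1.0 - e1) * (1.0 - e1);
    if (s0 > 0) d0 /= s0;
    if (s1 > 0) d1 /= s1;
  }
  double w0, w1;
  if (root_mode == 0) {        // weight states by relative D ("obs")
    double s = d0 + d1;
    if (s <= 0)
      return List::create(_["lnl"] = R_NegInf, _["failed"] = true,
                          _["n_clamped"] = n_clamped);
    w0 = d0 / s; w1 = d1 / s;
  } else if (root_mode == 1) { // equal weights
    w0 = 0.5; w1 = 0.5;
  } else {                     // user-supplied
    w0 = root_p[0]; w1 = root_p[1];
  }
  double lik = w0 * d0 + w1 * d1;
  double lnl = (lik > 0) ? std::log(lik) + logcomp : R_NegInf;
  return List::create(_["lnl"] = lnl, _["failed"] = false,
                      _["n_clamped"] = n_clamped,
                      _["root_E"] = NumericVector::create(e0, e1),
                      _["root_D"] = NumericVector::create(d0, d1));
}
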
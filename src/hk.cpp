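#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact fGn autocorrelation: rho_k = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2,
// filled for lags 0..n_lags into rho (length n_lags + 1).
static void fgn_rho_fill(double H, int n_lags, double *rho) {
  const double e = 2.0 * H;
  std::vector<double> g((size_t)n_lags + 2);
  g[0] = 0.0;
  for (int k = 1; k <= n_lags + 1; ++k) g[k] = std::pow((double)k, e);
  rho[0] = 1.0;
  for (int k = 1; k <= n_lags; ++k)
    rho[k] = 0.5 * (g[k + 1] - 2.0 * g[k] + g[k - 1]);
}

struct QuadForms {
  double xRx, eRe, eRx, logdet;
};

// Quadratic forms x'R^-1 x, e'R^-1 e, e'R^-1 x and ln|R| of the symmetric
// positive-definite Toeplitz matrix R defined by rho[0..n-1], via the Durbin
// recursion.  The rows of the prediction-error filter give the factorization
// R^-1 = A' D^-1 A, so both quadratic forms accumulate as innovations
// (one-step prediction errors) of x and of the ones vector, weighted by the
// prediction-error variances v_k; ln|R| = sum(ln v_k).  O(n^2) time, O(n)
// memory.  Returns false when a prediction-error variance becomes
// nonpositive (numerically non-positive-definite R).
static bool quadforms_core(const double *rho, const double *x, int n,
                           QuadForms *out) {
  double v = rho[0];
  if (v <= 0.0 || n < 1) return false;
  double xRx = 0.0, eRe = 0.0, eRx = 0.0, logdet = 0.0;
  double s = 0.0;  // running sum of prediction coefficients (O(1) update)
  {
    const double ex = x[0], ee = 1.0;
    xRx += ex * ex / v;
    eRe += ee * ee / v;
    eRx += ee * ex / v;
    logdet += std::log(v);
  }
  if (n == 1) {
    out->xRx = xRx; out->eRe = eRe; out->eRx = eRx; out->logdet = logdet;
    return true;
  }
  // b holds the order-m prediction coefficients in reversed (filter) order,
  // so both inner products below are contiguous forward dots.
  std::vector<double> bbuf(2 * (size_t)(n - 1));
  double *b = bbuf.data(), *bn = b + (n - 1);
  for (int m = 0; m < n - 1; ++m) {
    double acc = 0.0;
    for (int u = 0; u < m; ++u) acc += b[u] * rho[u + 1];
    const double kappa = (rho[m + 1] - acc) / v;
    bn[0] = kappa;
    double pred = kappa * x[0];  // innovation dot, fused with the update
    for (int j = 1; j <= m; ++j) {
      const double bj = b[j - 1] - kappa * b[m - j];
      bn[j] = bj;
      pred += bj * x[j];
    }
    v *= (1.0 - kappa * kappa);
    if (v <= 0.0 || !std::isfinite(v)) return false;
    s += kappa * (1.0 - s);
    const double ex = x[m + 1] - pred;
    const double ee = 1.0 - s;
    xRx += ex * ex / v;
    eRe += ee * ee / v;
    eRx += ee * ex / v;
    logdet += std::log(v);
    std::swap(b, bn);
  }
  out->xRx = xRx; out->eRe = eRe; out->eRx = eRx; out->logdet = logdet;
  return true;
}

// [[Rcpp::export(rng = false)]]
List hk_quadforms_cpp(NumericVector rho, NumericVector x) {
  const int n = x.size();
  if (rho.size() != n) stop("acf and series lengths must match");
  QuadForms qf;
  const bool ok = quadforms_core(REAL(rho), REAL(x), n, &qf);
  return List::create(_["xRx"] = ok ? qf.xRx : NA_REAL,
                      _["eRe"] = ok ? qf.eRe : NA_REAL,
                      _["eRx"] = ok ? qf.eRx : NA_REAL,
                      _["logdetR"] = ok ? qf.logdet : NA_REAL,
                      _["ok"] = ok);
}

// Unnormalized log marginal posterior of the Hurst exponent under the fGn
// likelihood with noninformative location/scale priors:
//   ln pi(h | x) = -1/2 ln|R| - (n-1)/2 ln(eRe*xRx - eRx^2) + (n/2-1) ln(eRe)
// up to an additive constant.  Returns -Inf outside (0,1) or when R(h) is
// numerically non-positive-definite.
// [[Rcpp::export(rng = false)]]
double hk_logpost_cpp(double h, NumericVector x) {
  const int n = x.size();
  if (!(h > 0.0 && h < 1.0) || n < 2) return R_NegInf;
  std::vector<double> rho((size_t)n);
  fgn_rho_fill(h, n - 1, rho.data());
  QuadForms qf;
  if (!quadforms_core(rho.data(), REAL(x), n, &qf)) return R_NegInf;
  const double bracket = qf.eRe * qf.xRx - qf.eRx * qf.eRx;
  if (!(bracket > 0.0) || !(qf.eRe > 0.0)) return R_NegInf;
  return -0.5 * qf.logdet - 0.5 * (n - 1) * std::log(bracket) +
         (0.5 * n - 1.0) * std::log(qf.eRe);
}

// Accept-reject sampling of H from the marginal posterior with a
// Uniform(0,1) proposal and envelope ln M = log_M.  Consumes R's RNG stream
// as (h, u) pairs, one pair per proposal.
// [[Rcpp::export]]
List hk_sample_cpp(NumericVector x, int n_samples, double log_M,
                   double max_proposals) {
  std::vector<double> acc;
  acc.reserve((size_t)n_samples);
  double best_rejected = R_NegInf;
  double n_prop = 0.0;
  while ((int)acc.size() < n_samples && n_prop < max_proposals) {
    const double h = unif_rand();
    const double u = unif_rand();
    n_prop += 1.0;
    const double lp = hk_logpost_cpp(h, x);
    if (std::log(u) <= lp - log_M) {
      acc.push_back(h);
    } else if (lp > best_rejected) {
      best_rejected = lp;
    }
  }
  return List::create(
      _["samples"] = NumericVector(acc.begin(), acc.end()),
      _["n_proposals"] = n_prop,
      _["ok"] = ((int)acc.size() == n_samples),
      _["best_rejected"] = best_rejected);
}
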
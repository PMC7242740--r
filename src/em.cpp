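#include <Rcpp.h>
using namespace Rcpp;

// One EM run for a 1-D Gaussian mixture from a given initialization.
// Returns the converged parameters, the log-likelihood evaluated at those
// parameters, the effective component counts, and a flag for runs that
// collapsed to an empty component.
// [[Rcpp::export]]
List em_gmm_1d(NumericVector x, NumericVector mu0, NumericVector pi0,
               NumericVector V0, double tol, int max_iter, double vfloor) {
  const int n = x.size();
  const int g = mu0.size();
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> logd(g), nk(g, 0.0), s1(g), s2(g), lc(g);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool empty = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < g; ++i)
      lc[i] = std::log(pi[i]) - 0.5 * std::log(2.0 * M_PI * V[i]);
    double llnew = 0.0;
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double m = R_NegInf;
      for (int i = 0; i < g; ++i) {
        const double d = x[j] - mu[i];
        logd[i] = lc[i] - d * d / (2.0 * V[i]);
        if (logd[i] > m) m = logd[i];
      }
      double s = 0.0;
      for (int i = 0; i < g; ++i) {
        logd[i] = std::exp(logd[i] - m);  // reuse as unnormalized resp.
        s += logd[i];
      }
      llnew += m + std::log(s);
      for (int i = 0; i < g; ++i) {
        const double rij = logd[i] / s;
        nk[i] += rij;
        s1[i] += rij * x[j];
        s2[i] += rij * x[j] * x[j];
      }
    }
    ll = llnew;
    for (int i = 0; i < g; ++i) if (nk[i] < 1e-10) empty = true;
    if (empty) break;
    for (int i = 0; i < g; ++i) {
      pi[i] = nk[i] / n;
      const double m1 = s1[i] / nk[i];
      mu[i] = m1;
      V[i] = std::max(s2[i] / nk[i] - m1 * m1, vfloor);
    }
    if (std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1.0)) break;
    ll_old = ll;
  }

  // final log-likelihood at the returned parameters
  if (!empty) {
    for (int i = 0; i < g; ++i)
      lc[i] = std::log(pi[i]) - 0.5 * std::log(2.0 * M_PI * V[i]);
    double llf = 0.0;
    for (int j = 0; j < n; ++j) {
      double m = R_NegInf;
      for (int i = 0; i < g; ++i) {
        const double d = x[j] - mu[i];
        logd[i] = lc[i] - d * d / (2.0 * V[i]);
        if (logd[i] > m) m = logd[i];
      }
      double s = 0.0;
      for (int i = 0; i < g; ++i) s += std::exp(logd[i] - m);
      llf += m + std::log(s);
    }
    ll = llf;
  }

  return List::create(_["pi"] = NumericVector(pi.begin(), pi.end()),
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["V"] = NumericVector(V.begin(), V.end()),
                      _["ll"] = ll,
                      _["nk"] = NumericVector(nk.begin(), nk.end()),
                      _["empty"] = empty);
}
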
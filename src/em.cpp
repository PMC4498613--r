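// Two-component normal-mixture ECM fits used by the QEI genome scan.
//
// Data: adjusted phenotypes dy (n x e, NA allowed), per-individual prior
// probabilities pi1 of the QQ genotype at the testing position (NA = the
// individual is excluded from this position's likelihood).  One genotype is
// shared across environments, so an individual's component density is the
// PRODUCT over its observed environments.
//
// fit H1: unconstrained means mu_kh, one variance per environment.
// fit H2: same model with the average effect constrained to zero,
//         sum_h (mu_1h - mu_2h) = 0, enforced each CM step through a single
//         Lagrange multiplier.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct FitResult {
  std::vector<double> mu1, mu2, sigma2;
  double loglik;
  int iterations;
  bool converged;
  double lagrange;
  std::vector<double> w1;   // posterior P(QQ) per individual
  double f1;                // mean posterior over included individuals
};

inline double log_norm(double x, double mu, double s2) {
  double d = x - mu;
  return -0.5 * (std::log(2.0 * M_PI * s2) + d * d / s2);
}

// One ECM fit; constrained == true adds the zero-average-effect constraint.
// sum_form == true replaces the product of per-environment densities in the
// posterior weights and monitored objective by their sum (comparison
// variant; the product form is the model whose ECM has these M-steps).
FitResult ecm_fit(const NumericMatrix& dy, const NumericVector& pi1,
                  NumericVector mu1, NumericVector mu2, NumericVector sigma2,
                  bool constrained, double tol, int maxit,
                  bool sum_form = false) {
  const int n = dy.nrow(), e = dy.ncol();
  std::vector<double> w1(n, NA_REAL);
  std::vector<double> m1(e), m2(e), W1h(e), W2h(e);
  double ll = R_NegInf, ll_old = R_NegInf, lambda = 0.0;
  int it = 0;
  bool converged = false;

  for (it = 1; it <= maxit; ++it) {
    // E-step and log-likelihood
    ll = 0.0;
    double sw1 = 0.0; int ninc = 0;
    std::fill(m1.begin(), m1.end(), 0.0);
    std::fill(m2.begin(), m2.end(), 0.0);
    std::fill(W1h.begin(), W1h.end(), 0.0);
    std::fill(W2h.begin(), W2h.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double p1 = pi1[i];
      if (ISNAN(p1)) { w1[i] = NA_REAL; continue; }
      double lf1 = 0.0, lf2 = 0.0;
      double sf1 = 0.0, sf2 = 0.0;
      bool any_obs = false;
      for (int h = 0; h < e; ++h) {
        double y = dy(i, h);
        if (ISNAN(y)) continue;
        any_obs = true;
        if (sum_form) {
          sf1 += std::exp(log_norm(y, mu1[h], sigma2[h]));
          sf2 += std::exp(log_norm(y, mu2[h], sigma2[h]));
        } else {
          lf1 += log_norm(y, mu1[h], sigma2[h]);
          lf2 += log_norm(y, mu2[h], sigma2[h]);
        }
      }
      if (!any_obs) { w1[i] = NA_REAL; continue; }
      if (sum_form) {
        lf1 = std::log(sf1 > 0 ? sf1 : 1e-300);
        lf2 = std::log(sf2 > 0 ? sf2 : 1e-300);
      }
      double a1 = std::log(p1 > 0 ? p1 : 1e-300) + lf1;
      double a2 = std::log(p1 < 1 ? 1.0 - p1 : 1e-300) + lf2;
      if (p1 <= 0) a1 = R_NegInf;
      if (p1 >= 1) a2 = R_NegInf;
      double mx = std::max(a1, a2);
      double s = std::exp(a1 - mx) + std::exp(a2 - mx);
      ll += mx + std::log(s);
      double w = std::exp(a1 - mx) / s;
      w1[i] = w;
      sw1 += w; ++ninc;
      for (int h = 0; h < e; ++h) {
        double y = dy(i, h);
        if (ISNAN(y)) continue;
        m1[h] += w * y;        W1h[h] += w;
        m2[h] += (1 - w) * y;  W2h[h] += 1 - w;
      }
    }

    if (std::abs(ll - ll_old) < tol && it > 1) { converged = true; break; }
    ll_old = ll;

    // CM-step: means
    for (int h = 0; h < e; ++h) {
      m1[h] = (W1h[h] > 1e-8) ? m1[h] / W1h[h] : mu1[h];
      m2[h] = (W2h[h] > 1e-8) ? m2[h] / W2h[h] : mu2[h];
    }
    if (!constrained) {
      for (int h = 0; h < e; ++h) { mu1[h] = m1[h]; mu2[h] = m2[h]; }
      lambda = 0.0;
    } else {
      double num = 0.0, den = 0.0;
      for (int h = 0; h < e; ++h) {
        num += m1[h] - m2[h];
        double inv1 = (W1h[h] > 1e-8) ? 1.0 / W1h[h] : 0.0;
        double inv2 = (W2h[h] > 1e-8) ? 1.0 / W2h[h] : 0.0;
        den += sigma2[h] * (inv1 + inv2);
      }
      lambda = (den > 0) ? 2.0 * e * num / den : 0.0;
      for (int h = 0; h < e; ++h) {
        double s1 = sigma2[h] * lambda / (2.0 * e);
        mu1[h] = (W1h[h] > 1e-8) ? m1[h] - s1 / W1h[h] : m1[h];
        mu2[h] = (W2h[h] > 1e-8) ? m2[h] + s1 / W2h[h] : m2[h];
      }
    }

    // CM-step: variances (1/n_h, weighted over both components)
    for (int h = 0; h < e; ++h) {
      double ss = 0.0; int nh = 0;
      for (int i = 0; i < n; ++i) {
        double w = w1[i], y = dy(i, h);
        if (ISNAN(w) || ISNAN(y)) continue;
        double d1 = y - mu1[h], d2 = y - mu2[h];
        ss += w * d1 * d1 + (1 - w) * d2 * d2;
        ++nh;
      }
      if (nh > 0 && ss > 0) sigma2[h] = ss / nh;
      if (sigma2[h] < 1e-12) sigma2[h] = 1e-12;
    }
  }

  FitResult out;
  out.mu1.assign(mu1.begin(), mu1.end());
  out.mu2.assign(mu2.begin(), mu2.end());
  out.sigma2.assign(sigma2.begin(), sigma2.end());
  out.loglik = ll;
  out.iterations = it;
  out.converged = converged;
  out.lagrange = lambda;
  out.w1 = w1;
  double sw = 0.0; int ninc = 0;
  for (int i = 0; i < n; ++i)
    if (!ISNAN(w1[i])) { sw += w1[i]; ++ninc; }
  out.f1 = (ninc > 0) ? sw / ninc : NA_REAL;
  return out;
}

List wrap_fit(const FitResult& f) {
  return List::create(
    _["mu1"] = f.mu1, _["mu2"] = f.mu2, _["sigma2"] = f.sigma2,
    _["loglik"] = f.loglik, _["iterations"] = f.iterations,
    _["converged"] = f.converged, _["lagrange"] = f.lagrange,
    _["w1"] = f.w1, _["f1"] = f.f1);
}

} // namespace

// [[Rcpp::export]]
List cpp_fit_mixture(NumericMatrix dy, NumericVector pi1,
                     NumericVector mu1, NumericVector mu2,
                     NumericVector sigma2, bool constrained,
                     double tol, int maxit, bool sum_form = false) {
  return wrap_fit(ecm_fit(dy, pi1, clone(mu1), clone(mu2), clone(sigma2),
                          constrained, tol, maxit, sum_form));
}

// Scan all testing positions of one interval: pi1 columns are positions.
// Returns matrices of fitted means and vectors of log-likelihoods for the
// unconstrained (H1) and constrained (H2) fits at every position.
// [[Rcpp::export]]
List cpp_scan_interval(NumericMatrix dy, NumericMatrix pi1_mat,
                       NumericVector mu1_0, NumericVector mu2_0,
                       NumericVector sigma2_0, double tol, int maxit,
                       bool sum_form = false) {
  const int e = dy.ncol(), npos = pi1_mat.ncol();
  NumericMatrix mu1(npos, e), mu2(npos, e), sigma2(npos, e);
  NumericVector ll1(npos), ll2(npos), f1(npos), lagrange(npos);
  IntegerVector it1(npos), it2(npos);
  LogicalVector conv1(npos), conv2(npos);
  for (int p = 0; p < npos; ++p) {
    NumericVector pi1 = pi1_mat(_, p);
    FitResult h1 = ecm_fit(dy, pi1, clone(mu1_0), clone(mu2_0),
                           clone(sigma2_0), false, tol, maxit, sum_form);
    FitResult h2 = ecm_fit(dy, pi1, clone(mu1_0), clone(mu2_0),
                           clone(sigma2_0), true, tol, maxit, sum_form);
    for (int h = 0; h < e; ++h) {
      mu1(p, h) = h1.mu1[h];
      mu2(p, h) = h1.mu2[h];
      sigma2(p, h) = h1.sigma2[h];
    }
    ll1[p] = h1.loglik;  ll2[p] = h2.loglik;
    f1[p] = h1.f1;       lagrange[p] = h2.lagrange;
    it1[p] = h1.iterations; it2[p] = h2.iterations;
    conv1[p] = h1.converged; conv2[p] = h2.converged;
  }
  return List::create(
    _["mu1"] = mu1, _["mu2"] = mu2, _["sigma2"] = sigma2,
    _["ll1"] = ll1, _["ll2"] = ll2, _["f1"] = f1,
    _["lagrange"] = lagrange,
    _["iterations1"] = it1, _["iterations2"] = it2,
    _["converged1"] = conv1, _["converged2"] = conv2);
}
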
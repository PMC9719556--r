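// EM inner loop for univariate skew-normal / normal mixtures.
// Parameterisation: component j has weight w, location xi, scale omega,
// shape alpha; density 2/omega phi(z) Phi(alpha z), z = (x - xi)/omega.
// The skew-normal M-step uses the truncated-normal latent representation
// x = xi + tau |t| + sqrt(Gamma) e with tau = omega delta,
// Gamma = omega^2 (1 - delta^2), delta = alpha / sqrt(1 + alpha^2).
#include <Rcpp.h>
using namespace Rcpp;

#ifndef M_LN_SQRT_2PI
#define M_LN_SQRT_2PI 0.918938533204672741780329736406
#endif

static inline double log_dnorm(double z) {
  return -0.5 * z * z - M_LN_SQRT_2PI;
}

// log Phi(u) via erfc, with the classic asymptotic series deep in the left
// tail where erfc underflows
static inline double log_pnorm(double u) {
  if (u >= 0.0) return std::log1p(-0.5 * std::erfc(u * M_SQRT1_2));
  if (u > -26.0) return std::log(0.5 * std::erfc(-u * M_SQRT1_2));
  const double u2 = u * u;
  return log_dnorm(u) - std::log(-u) + std::log1p(-1.0 / u2 + 3.0 / (u2 * u2));
}

static inline double inv_mills(double u) {
  // phi(u) / Phi(u), stable far into the left tail
  return std::exp(log_dnorm(u) - log_pnorm(u));
}

// [[Rcpp::export]]
List em_smsn_cpp(NumericVector x, int g, bool skew, double tol, int max_iter,
                 NumericVector w0, NumericVector xi0, NumericVector omega0,
                 NumericVector alpha0) {
  const int n = x.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> xi(xi0.begin(), xi0.end());
  std::vector<double> omega(omega0.begin(), omega0.end());
  std::vector<double> alpha(alpha0.begin(), alpha0.end());

  std::vector<double> logd(static_cast<size_t>(n) * g);
  std::vector<double> Z(static_cast<size_t>(n) * g);
  std::vector<double> e1(n), e2(n);

  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false, failed = false;
  int iter = 0;

  for (;;) {
    ++iter;
    // E-step: log component densities, responsibilities, log-likelihood
    for (int j = 0; j < g; ++j) {
      const double lw = std::log(w[j]), lo = std::log(omega[j]);
      for (int i = 0; i < n; ++i) {
        const double z = (x[i] - xi[j]) / omega[j];
        double ld = log_dnorm(z) - lo;
        if (skew) ld += M_LN2 + log_pnorm(alpha[j] * z);
        logd[i + static_cast<size_t>(n) * j] = ld + lw;
      }
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < g; ++j)
        mx = std::max(mx, logd[i + static_cast<size_t>(n) * j]);
      double s = 0.0;
      for (int j = 0; j < g; ++j) {
        const double e = std::exp(logd[i + static_cast<size_t>(n) * j] - mx);
        Z[i + static_cast<size_t>(n) * j] = e;
        s += e;
      }
      for (int j = 0; j < g; ++j) Z[i + static_cast<size_t>(n) * j] /= s;
      ll += mx + std::log(s);
    }
    if (!std::isfinite(ll)) { failed = true; break; }
    if (std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + tol)) {
      converged = true;
      break;
    }
    if (iter >= max_iter) break;
    ll_old = ll;

    // M-step
    for (int j = 0; j < g; ++j) {
      double *zj = &Z[static_cast<size_t>(n) * j];
      double sumz = 0.0;
      for (int i = 0; i < n; ++i) sumz += zj[i];
      if (sumz < 1e-8) { failed = true; break; }
      w[j] = sumz / n;

      if (!skew) {
        double m = 0.0;
        for (int i = 0; i < n; ++i) m += zj[i] * x[i];
        m /= sumz;
        double v = 0.0;
        for (int i = 0; i < n; ++i) v += zj[i] * (x[i] - m) * (x[i] - m);
        xi[j] = m;
        omega[j] = std::sqrt(v / sumz);
        if (!(omega[j] > 1e-8)) { failed = true; break; }
        continue;
      }

      const double delta = alpha[j] / std::sqrt(1.0 + alpha[j] * alpha[j]);
      const double tau = omega[j] * delta;
      const double Gam = omega[j] * omega[j] * (1.0 - delta * delta);
      const double s = std::sqrt(Gam) / omega[j];  // sqrt(Gam/(Gam + tau^2))
      double num_xi = 0.0;
      for (int i = 0; i < n; ++i) {
        const double m = tau * (x[i] - xi[j]) / (omega[j] * omega[j]);
        const double h = inv_mills(m / s);
        e1[i] = m + s * h;
        e2[i] = m * m + s * s + m * s * h;
        num_xi += zj[i] * (x[i] - tau * e1[i]);
      }
      const double xin = num_xi / sumz;
      double num_tau = 0.0, den_tau = 0.0;
      for (int i = 0; i < n; ++i) {
        num_tau += zj[i] * e1[i] * (x[i] - xin);
        den_tau += zj[i] * e2[i];
      }
      const double taun = num_tau / den_tau;
      double gam_acc = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - xin;
        gam_acc += zj[i] * (d * d - 2.0 * taun * e1[i] * d + taun * taun * e2[i]);
      }
      const double Gamn = gam_acc / sumz;
      if (!std::isfinite(Gamn) || Gamn < 1e-10) { failed = true; break; }
      xi[j] = xin;
      omega[j] = std::sqrt(Gamn + taun * taun);
      alpha[j] = taun / std::sqrt(Gamn);
      if (!std::isfinite(xi[j]) || !std::isfinite(alpha[j]) ||
          !(omega[j] > 1e-8)) { failed = true; break; }
    }
    if (failed) break;
  }

  return List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["xi"] = NumericVector(xi.begin(), xi.end()),
    _["omega"] = NumericVector(omega.begin(), omega.end()),
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["loglik"] = ll, _["converged"] = converged, _["iter"] = iter,
    _["failed"] = failed);
}
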
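#include <Rcpp.h>
using namespace Rcpp;

// Univariate Gaussian mixture EM with unequal component variances.
// The E step and the log-likelihood are fused into a single pass with an
// inlined normal density, since the parametric-bootstrap LRT refits the
// model tens of thousands of times. Standard deviations are floored at
// sd_floor to avoid the usual likelihood singularities when a component
// collapses onto one point.

static const double INV_SQRT_2PI = 0.3989422804014327;

// [[Rcpp::export(name = ".em_gmm_cpp")]]
List em_gmm_cpp(NumericVector x, NumericVector mu0, NumericVector sd0,
                NumericVector w0, double tol, int maxit, double sd_floor,
                bool monotone_check) {
  const int n = x.size(), G = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> w(w0.begin(), w0.end());
  for (int g = 0; g < G; ++g) if (sd[g] < sd_floor) sd[g] = sd_floor;

  std::vector<double> resp(static_cast<size_t>(n) * G);
  std::vector<double> amp(G), inv2v(G);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false, monotone = true;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    for (int g = 0; g < G; ++g) {
      amp[g] = w[g] * INV_SQRT_2PI / sd[g];
      inv2v[g] = 0.5 / (sd[g] * sd[g]);
    }
    // E step + log-likelihood in one pass
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int g = 0; g < G; ++g) {
        double d = x[i] - mu[g];
        double val = amp[g] * std::exp(-d * d * inv2v[g]);
        resp[static_cast<size_t>(i) * G + g] = val;
        tot += val;
      }
      if (tot <= 0) {
        tot = DBL_MIN;
        resp[static_cast<size_t>(i) * G] = DBL_MIN;
      }
      ll += std::log(tot);
      double inv_tot = 1.0 / tot;
      for (int g = 0; g < G; ++g)
        resp[static_cast<size_t>(i) * G + g] *= inv_tot;
    }
    if (monotone_check && iter > 1 &&
        ll < ll_old - 1e-8 * (std::fabs(ll_old) + 1.0))
      monotone = false;
    if (iter > 1 &&
        std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1.0)) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M step
    for (int g = 0; g < G; ++g) {
      double nk = 0.0, sum = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = resp[static_cast<size_t>(i) * G + g];
        nk += r;
        sum += r * x[i];
      }
      if (nk <= 0) nk = DBL_MIN;
      double m = sum / nk, ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m;
        ss += resp[static_cast<size_t>(i) * G + g] * d * d;
      }
      mu[g] = m;
      sd[g] = std::sqrt(ss / nk);
      if (sd[g] < sd_floor) sd[g] = sd_floor;
      w[g] = nk / n;
    }
  }
  // On a maxit exit the reported loglik is the one computed just before
  // the final M step (a hair below the true value of the returned
  // parameters, since each M step can only increase it).
  return List::create(_["means"] = NumericVector(mu.begin(), mu.end()),
                      _["sds"] = NumericVector(sd.begin(), sd.end()),
                      _["weights"] = NumericVector(w.begin(), w.end()),
                      _["loglik"] = ll,
                      _["n_iterations"] = std::min(iter, maxit),
                      _["converged"] = converged, _["monotone"] = monotone);
}
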
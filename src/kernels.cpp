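// Numerical kernels for the constrained skew-normal mixture fit: the
// mixture E-step, the conditional truncated-normal moments of the
// stochastic representation, and the grid part of the pairwise
// density-dominance check. These sit in the innermost ECM loop.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sn_logpdf(double x, double mu, double sigma,
                               double lambda) {
  double z = (x - mu) / sigma;
  return M_LN2 - std::log(sigma) + R::dnorm(z, 0.0, 1.0, 1) +
         R::pnorm(lambda * z, 0.0, 1.0, 1, 1);
}

// [[Rcpp::export]]
NumericVector cpp_sn_logpdf(NumericVector x, double mu, double sigma,
                            double lambda) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = sn_logpdf(x[i], mu, sigma, lambda);
  return out;
}

// Posterior responsibilities and data log-likelihood of one mixture sample
// in a single pass. mu/sigma/lambda/logw have one entry per component;
// wt carries per-observation multiplicities (all 1 for raw scores, counts
// for binned scores) and scales the log-likelihood only.
// [[Rcpp::export]]
List cpp_estep(NumericVector s, NumericVector mu, NumericVector sigma,
               NumericVector lambda, NumericVector logw, NumericVector wt) {
  R_xlen_t n = s.size();
  int k = mu.size();
  NumericMatrix resp(n, k);
  double ll = 0.0;
  std::vector<double> row(k);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mx = R_NegInf;
    for (int j = 0; j < k; ++j) {
      row[j] = logw[j] + sn_logpdf(s[i], mu[j], sigma[j], lambda[j]);
      if (row[j] > mx) mx = row[j];
    }
    double sum = 0.0;
    for (int j = 0; j < k; ++j) {
      row[j] = std::exp(row[j] - mx);
      sum += row[j];
    }
    for (int j = 0; j < k; ++j) resp(i, j) = row[j] / sum;
    ll += wt[i] * (mx + std::log(sum));
  }
  return List::create(_["resp"] = resp, _["loglik"] = ll);
}

// First two conditional moments of the latent TN+(alpha, psi^2) variable,
// with alpha = (delta/sigma)(s - mu), psi^2 = 1 - delta^2; the inverse
// Mills ratio is evaluated in log space for left-tail stability.
// [[Rcpp::export]]
NumericMatrix cpp_tn_moments(NumericVector s, double mu, double sigma,
                             double lambda) {
  R_xlen_t n = s.size();
  double delta = lambda / std::sqrt(1.0 + lambda * lambda);
  double psi = std::sqrt(1.0 - delta * delta);
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double alpha = delta * (s[i] - mu) / sigma;
    double x = alpha / psi;
    double r = std::exp(R::dnorm(x, 0.0, 1.0, 1) -
                        R::pnorm(x, 0.0, 1.0, 1, 1));
    out(i, 0) = alpha + psi * r;
    out(i, 1) = alpha * alpha + psi * psi + alpha * psi * r;
  }
  return out;
}

static inline double logdiff(double x, double muF, double sigF, double lamF,
                             double muG, double sigG, double lamG) {
  return sn_logpdf(x, muF, sigF, lamF) - sn_logpdf(x, muG, sigG, lamG);
}

// Golden-section minimization of the log-density difference on [lo, hi];
// returns the minimal value found.
static double golden_min(double lo, double hi, double muF, double sigF,
                         double lamF, double muG, double sigG, double lamG) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = logdiff(x1, muF, sigF, lamF, muG, sigG, lamG);
  double f2 = logdiff(x2, muF, sigF, lamF, muG, sigG, lamG);
  for (int it = 0; it < 60 && (b - a) > 1e-10 * (hi - lo + 1e-300); ++it) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = logdiff(x1, muF, sigF, lamF, muG, sigG, lamG);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = logdiff(x2, muF, sigF, lamF, muG, sigG, lamG);
    }
  }
  return std::min(f1, f2);
}

// Grid part of the dominance check f > g: log f - log g must be positive
// on a quadratically spaced grid right of mode(f) and negative left of
// mode(g); interior local minima (maxima on the left) are polished by
// golden-section search.
// [[Rcpp::export]]
bool cpp_dominance_grid_ok(double muF, double sigF, double lamF,
                           double muG, double sigG, double lamG,
                           double modeF, double modeG,
                           int n_grid, double window) {
  double scale = std::max(sigF, sigG);
  std::vector<double> xs(n_grid), d(n_grid);
  // right side: d > 0 required
  for (int i = 0; i < n_grid; ++i) {
    double u = (double)i / (n_grid - 1);
    xs[i] = modeF + window * scale * u * u;
    d[i] = logdiff(xs[i], muF, sigF, lamF, muG, sigG, lamG);
    if (d[i] <= 0.0) return false;
  }
  for (int i = 1; i + 1 < n_grid; ++i) {
    if (d[i] <= d[i - 1] && d[i] <= d[i + 1]) {
      if (golden_min(xs[i - 1], xs[i + 1], muF, sigF, lamF,
                     muG, sigG, lamG) <= 0.0)
        return false;
    }
  }
  // left side: d < 0 required (equivalently log g - log f > 0)
  for (int i = 0; i < n_grid; ++i) {
    double u = (double)i / (n_grid - 1);
    xs[i] = modeG - window * scale * u * u;
    d[i] = logdiff(xs[i], muG, sigG, lamG, muF, sigF, lamF);
    if (d[i] <= 0.0) return false;
  }
  for (int i = 1; i + 1 < n_grid; ++i) {
    if (d[i] <= d[i - 1] && d[i] <= d[i + 1]) {
      if (golden_min(std::min(xs[i - 1], xs[i + 1]),
                     std::max(xs[i - 1], xs[i + 1]),
                     muG, sigG, lamG, muF, sigF, lamF) <= 0.0)
        return false;
    }
  }
  return true;
}
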
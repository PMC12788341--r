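#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Penalized logistic regression by IRLS + cyclic coordinate descent with
// soft-thresholding. Objective per lambda:
//   (1/n) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ] + lambda * sum_j |beta_j|
// with an unpenalized intercept. Lambdas are visited in the order given;
// callers pass them descending so each solution warm-starts the next.
//
// Each IRLS quadratic is solved in covariance form: with n >> p the inner
// sweeps then cost O(p) per coordinate instead of O(n).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// one penalized weighted-least-squares problem in covariance form:
//   minimize 0.5 sum_i w_i (z_i - b0 - x_i'beta)^2 + pen * sum_{penalized} |beta_j|
// G = X'WX, cx = X'Wz, gx = X'W1, wz = 1'Wz, wsum = 1'W1
static void cd_quadratic(const std::vector<double>& G,
                         const std::vector<double>& cx,
                         const std::vector<double>& gx,
                         double wz, double wsum, double pen,
                         const std::vector<bool>& penalize,
                         double& b0, std::vector<double>& beta,
                         double tol, int max_inner, double& first_change) {
  const int p = beta.size();
  std::vector<double> s(p, 0.0);   // s = G beta
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      for (int k = 0; k < p; ++k) s[k] += G[k + j * p] * beta[j];
    }
  }
  first_change = 0.0;
  for (int inner = 0; inner < max_inner; ++inner) {
    double max_change = 0.0;
    if (wsum > 0.0) {
      double sb = 0.0;
      for (int j = 0; j < p; ++j) sb += gx[j] * beta[j];
      double nb0 = (wz - sb) / wsum;
      double d = nb0 - b0;
      if (d != 0.0) {
        b0 = nb0;
        if (std::fabs(d) > max_change) max_change = std::fabs(d);
      }
    }
    for (int j = 0; j < p; ++j) {
      const double Gjj = G[j + j * p];
      if (Gjj <= 0.0) { beta[j] = 0.0; continue; }
      double r = cx[j] - gx[j] * b0 - s[j] + Gjj * beta[j];
      double nbj = penalize[j] ? soft(r, pen) / Gjj : r / Gjj;
      double d = nbj - beta[j];
      if (d != 0.0) {
        for (int k = 0; k < p; ++k) s[k] += G[k + j * p] * d;
        beta[j] = nbj;
        if (std::fabs(d) > max_change) max_change = std::fabs(d);
      }
    }
    if (inner == 0) first_change = max_change;
    if (max_change < tol) break;
  }
}

// [[Rcpp::export]]
List l1_logistic_path_cpp(const NumericMatrix& X, const NumericVector& y,
                          const NumericVector& lambda,
                          double tol, int max_outer, int max_inner,
                          NumericVector beta_init, double intercept_init) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  NumericMatrix coefs(p + 1, nl);   // row 0 = intercept
  IntegerVector iters(nl);
  LogicalVector conv(nl);

  std::vector<double> beta(p), eta(n), w(n), z(n), u(n);
  std::vector<double> G(p * p), cx(p), gx(p);
  std::vector<bool> pen_all(p, true);
  const double* Xp = X.begin();   // column-major data
  double b0 = intercept_init;
  for (int j = 0; j < p; ++j) beta[j] = beta_init[j];

  for (int l = 0; l < nl; ++l) {
    const double pen = lambda[l] * n;   // penalty on the sum-NLL scale
    bool converged = false;
    int outer = 0;
    for (outer = 0; outer < max_outer && !converged; ++outer) {
      // linear predictor and IRLS transform at the current coefficients
      for (int i = 0; i < n; ++i) eta[i] = b0;
      for (int j = 0; j < p; ++j) {
        const double bj = beta[j];
        const double* xj = Xp + (size_t)j * n;
        if (bj != 0.0) for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
      }
      double wsum = 0.0, wz = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = eta[i];
        if (e > 30) e = 30; else if (e < -30) e = -30;
        double pr = 1.0 / (1.0 + std::exp(-e));
        double wi = pr * (1.0 - pr);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        wsum += wi;
        z[i] = eta[i] + (y[i] - pr) / wi;
        wz += wi * z[i];
      }
      // weighted moments (covariance form); u = W x_j reused across k
      for (int j = 0; j < p; ++j) {
        const double* xj = Xp + (size_t)j * n;
        double cj = 0.0, gj = 0.0;
        for (int i = 0; i < n; ++i) {
          const double wx = w[i] * xj[i];
          u[i] = wx;
          cj += wx * z[i];
          gj += wx;
        }
        cx[j] = cj;
        gx[j] = gj;
        for (int k = 0; k <= j; ++k) {
          const double* xk = Xp + (size_t)k * n;
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += u[i] * xk[i];
          G[j + k * p] = s;
          G[k + j * p] = s;
        }
      }
      double first_change = 0.0;
      cd_quadratic(G, cx, gx, wz, wsum, pen, pen_all, b0, beta,
                   tol, max_inner, first_change);
      if (first_change < tol) converged = true;
    }
    conv[l] = converged;
    iters[l] = outer;
    coefs(0, l) = b0;
    for (int j = 0; j < p; ++j) coefs(j + 1, l) = beta[j];
  }
  return List::create(_["coefficients"] = coefs, _["iterations"] = iters,
                      _["converged"] = conv);
}

// Penalized weighted least squares coordinate-descent step used as the
// fixed-effects block update inside the mixed-model fitter. Minimizes
//   0.5 * sum_i w_i (z_i - b0 - x_i'beta)^2 + lambda * sum_{j penalized} |beta_j|
// (unscaled penalty, matching the mixed model's unscaled objective).

// [[Rcpp::export]]
NumericVector cd_wls_l1_cpp(const NumericMatrix& X, const NumericVector& z,
                            const NumericVector& w, double lambda,
                            const LogicalVector& penalize,
                            NumericVector start, double tol, int max_it) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(p), G(p * p), cx(p), gx(p), u(n);
  std::vector<bool> pen(p);
  const double* Xp = X.begin();
  double b0 = start[0], wsum = 0.0, wz = 0.0;
  for (int j = 0; j < p; ++j) {
    beta[j] = start[j + 1];
    pen[j] = penalize[j];
  }
  for (int i = 0; i < n; ++i) {
    wsum += w[i];
    wz += w[i] * z[i];
  }
  for (int j = 0; j < p; ++j) {
    const double* xj = Xp + (size_t)j * n;
    double cj = 0.0, gj = 0.0;
    for (int i = 0; i < n; ++i) {
      const double wx = w[i] * xj[i];
      u[i] = wx;
      cj += wx * z[i];
      gj += wx;
    }
    cx[j] = cj;
    gx[j] = gj;
    for (int k = 0; k <= j; ++k) {
      const double* xk = Xp + (size_t)k * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += u[i] * xk[i];
      G[j + k * p] = s;
      G[k + j * p] = s;
    }
  }
  double first_change = 0.0;
  cd_quadratic(G, cx, gx, wz, wsum, lambda, pen, b0, beta, tol, max_it,
               first_change);
  NumericVector out(p + 1);
  out[0] = b0;
  for (int j = 0; j < p; ++j) out[j + 1] = beta[j];
  return out;
}
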
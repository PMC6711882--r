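#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual with an RBF kernel,
// maximal-violating-pair working-set selection. Dense kernel matrix is
// precomputed: intended for per-subject EEG problems (n up to a few
// thousand), not large-scale learning.
//
// Dual: min 0.5 a'Qa - e'a  s.t. 0 <= a_i <= C, y'a = 0,
// with Q_ij = y_i y_j K(x_i, x_j), K = exp(-gamma ||x_i - x_j||^2).

static inline double rbf(const NumericMatrix &X, int i, int j, double gamma) {
  double s = 0.0;
  int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
                   double tol = 1e-3, int max_iter = 100000) {
  int n = X.nrow();
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i) {
    K[static_cast<size_t>(i) * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = rbf(X, i, j, gamma);
      K[static_cast<size_t>(i) * n + j] = v;
      K[static_cast<size_t>(j) * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Qa - e
  int iter = 0;
  while (iter < max_iter) {
    // working set: i = argmax_{t in I_up} -y_t G_t ; j = argmin_{t in I_low} -y_t G_t
    int i = -1, j = -1;
    double gmax = -INFINITY, gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    const double *Ki = &K[static_cast<size_t>(i) * n];
    const double *Kj = &K[static_cast<size_t>(j) * n];
    double quad = Ki[i] + Kj[j] - 2.0 * y[i] * y[j] * Ki[j];
    if (quad <= 0) quad = 1e-12;
    double delta = (gmax - gmin) / quad; // step along (y_i e_i - y_j e_j)

    double ai_old = alpha[i], aj_old = alpha[j];
    double ai = ai_old + y[i] * delta;
    double aj = aj_old - y[j] * delta;
    // clip to the box, preserving y'a = 0
    if (ai < 0) ai = 0; else if (ai > C) ai = C;
    double step_i = y[i] * (ai - ai_old);
    aj = aj_old - y[j] * step_i;
    if (aj < 0) aj = 0; else if (aj > C) aj = C;
    double step_j = y[j] * (aj - aj_old);
    ai = ai_old + y[i] * (-step_j);
    alpha[i] = ai;
    alpha[j] = aj;

    double di = y[i] * (ai - ai_old), dj = y[j] * (aj - aj_old);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (Ki[t] * di + Kj[t] * dj);
    ++iter;
  }

  // intercept: -y_t G_t is constant over free SVs at the optimum; average
  // those, or fall back to the midpoint of the feasible interval
  double bsum = 0.0; int nfree = 0;
  double vmax = -INFINITY, vmin = INFINITY;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { bsum += v; ++nfree; }
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (up && v > vmax) vmax = v;
    if (low && v < vmin) vmin = v;
  }
  double b = nfree > 0 ? bsum / nfree : (vmax + vmin) / 2.0;

  NumericVector alpha_out(n);
  for (int t = 0; t < n; ++t) alpha_out[t] = alpha[t];
  return List::create(_["alpha"] = alpha_out, _["b"] = b,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}

// [[Rcpp::export]]
NumericVector svm_rbf_decision(NumericMatrix SV, NumericVector coef, double b,
                               double gamma, NumericMatrix newX) {
  int nsv = SV.nrow(), m = newX.nrow(), d = SV.ncol();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = b;
    for (int s = 0; s < nsv; ++s) {
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = newX(i, k) - SV(s, k);
        dist += diff * diff;
      }
      acc += coef[s] * std::exp(-gamma * dist);
    }
    out[i] = acc;
  }
  return out;
}
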
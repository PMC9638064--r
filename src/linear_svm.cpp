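// Linear SVM via dual coordinate descent (L2-regularized L1-loss, the
// liblinear algorithm), with the intercept handled as an augmented
// constant feature. Compiled because the incremental-feature-selection
// protocol refits the classifier N times per candidate panel under
// leave-one-out cross-validation.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline uint32_t xorshift(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// Z: n x d column-major (bias column included), y in {-1,+1}.
// Writes the d-vector w. Deterministic: fixed internal shuffle seed.
static void dcd_fit(const double *Z, const int *y, int n, int d,
                    double C, double tol, int max_epochs, double *w) {
  std::vector<double> alpha(n, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int j = 0; j < d; ++j) { double v = Z[i + (size_t)j * n]; s += v * v; }
    Qii[i] = s;
  }
  for (int j = 0; j < d; ++j) w[j] = 0.0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  uint32_t rng = 88172645u;
  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xorshift(rng) % (uint32_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      if (Qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * Z[i + (size_t)j * n];
      g = g * y[i] - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = g < 0.0 ? g : 0.0;
      else if (alpha[i] >= C) pg = g > 0.0 ? g : 0.0;
      double apg = std::fabs(pg);
      if (apg > max_pg) max_pg = apg;
      if (apg > 1e-12) {
        double old = alpha[i];
        double anew = old - g / Qii[i];
        if (anew < 0.0) anew = 0.0; else if (anew > C) anew = C;
        alpha[i] = anew;
        double delta = (anew - old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * Z[i + (size_t)j * n];
      }
    }
    if (max_pg < tol) break;
  }
}

// [[Rcpp::export]]
NumericVector cpp_linear_svm_fit(NumericMatrix Z, IntegerVector y,
                                 double cost, double tol, int max_epochs) {
  int n = Z.nrow(), d = Z.ncol();
  if (y.size() != n) stop("y length does not match rows of Z");
  NumericVector w(d);
  dcd_fit(REAL(Z), INTEGER(y), n, d, cost, tol, max_epochs, REAL(w));
  return w;
}

// Full leave-one-out loop: per fold, refit feature standardization on
// the n-1 training cells (sample sd; constant features zeroed), fit the
// SVM, predict the held-out cell. Returns predictions in {-1,+1}, the
// fold/fit counter, and how many folds were degenerate (single-class
// training set -> majority-class prediction).
// [[Rcpp::export]]
List cpp_linear_svm_loocv(NumericMatrix X, IntegerVector y, double cost,
                          double bias, double tol, int max_epochs) {
  int n = X.nrow(), k = X.ncol();
  if (y.size() != n) stop("y length does not match rows of X");
  if (n < 3) stop("LOOCV needs at least 3 cells");
  const double *x = REAL(X);
  std::vector<double> colsum(k, 0.0), colsq(k, 0.0);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) {
      double v = x[i + (size_t)j * n];
      colsum[j] += v; colsq[j] += v * v;
    }
  int npos = 0;
  for (int i = 0; i < n; ++i) npos += (y[i] > 0);

  int d = k + 1;                       // + bias column
  int m = n - 1;
  std::vector<double> Z((size_t)m * d), w(d), mu(k), sd(k);
  std::vector<int> ytr(m);
  IntegerVector pred(n);
  int degenerate = 0, n_fits = 0;

  for (int hold = 0; hold < n; ++hold) {
    int npos_tr = npos - (y[hold] > 0);
    ++n_fits;
    if (npos_tr == 0 || npos_tr == m) {   // single-class training fold
      pred[hold] = npos_tr == 0 ? -1 : 1;
      ++degenerate;
      continue;
    }
    for (int j = 0; j < k; ++j) {
      double v = x[hold + (size_t)j * n];
      double mj = (colsum[j] - v) / m;
      double var = (colsq[j] - v * v - (double)m * mj * mj) / (m - 1);
      mu[j] = mj;
      sd[j] = var > 1e-24 ? std::sqrt(var) : 0.0;
    }
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int j = 0; j < k; ++j) {
        double v = x[i + (size_t)j * n];
        Z[r + (size_t)j * m] = sd[j] > 0.0 ? (v - mu[j]) / sd[j] : 0.0;
      }
      Z[r + (size_t)k * m] = bias;
      ytr[r] = y[i];
      ++r;
    }
    dcd_fit(Z.data(), ytr.data(), m, d, cost, tol, max_epochs, w.data());
    double dec = w[k] * bias;
    for (int j = 0; j < k; ++j) {
      if (sd[j] > 0.0)
        dec += w[j] * (x[hold + (size_t)j * n] - mu[j]) / sd[j];
    }
    pred[hold] = dec >= 0.0 ? 1 : -1;
  }
  return List::create(_["predicted"] = pred,
                      _["n_fits"] = n_fits,
                      _["degenerate_folds"] = degenerate);
}
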
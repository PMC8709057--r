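#include <Rcpp.h>
using namespace Rcpp;

// Dual SVM solver: sequential minimal optimization with maximal-violating-
// pair working-set selection on a precomputed kernel matrix.
//
// Solves   min_a 0.5 a' Q a - e' a,  Q_ij = y_i y_j K_ij,
//          s.t. y' a = 0, 0 <= a_i <= C.
//
// Returns alpha, the bias b (decision value f(x) = sum_i a_i y_i K(x_i, x)
// + b), the iteration count and the final KKT violation gap.

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix must be square and match y");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  double m = 0.0, M = 0.0;
  const double TAU = 1e-12;

  while (iter < max_iter) {
    // working-set selection: most violating pair
    int i = -1, j = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      const double v = -y[t] * G[t];
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      // Q_ii + Q_jj + 2 Q_ij, with Q_ij = y_i y_j K_ij (= -K_ij here)
      double quad = K(i, i) + K(j, j) + 2.0 * y[i] * y[j] * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      // Q_ii + Q_jj - 2 Q_ij = K_ii + K_jj - 2 K_ij when y_i == y_j
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double di = (alpha[i] - ai_old) * y[i];
    const double dj = (alpha[j] - aj_old) * y[j];
    if (di != 0.0 || dj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (K(t, i) * di + K(t, j) * dj);
    }
    ++iter;
  }

  // bias: average -y_t G_t over free support vectors, else midpoint
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > TAU && alpha[t] < C - TAU) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) b /= nfree;
  else b = (m + M) / 2.0;

  return List::create(_["alpha"] = alpha, _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m - M);
}
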
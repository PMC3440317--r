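#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sequential minimal optimisation for the C-SVC dual with a precomputed
// kernel matrix. Working-set selection is the classic maximal-violating
// pair; the full gradient is maintained, so one iteration costs O(n).
//
// Dual problem: min_a 1/2 a'Qa - e'a, Q_ij = y_i y_j K_ij,
//               0 <= a_i <= C, sum_i y_i a_i = 0.
//
// Returns alpha, the bias rho (decision f(x) = sum_i y_i a_i K(x_i,x) - rho),
// the final KKT gap and the iteration count.
// [[Rcpp::export]]
List smo_csvc(NumericMatrix K, IntegerVector y, double C,
              double tol = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("labels must match kernel dimension");
  for (int i = 0; i < n; ++i)
    if (y[i] != 1 && y[i] != -1) stop("labels must be +1/-1");
  if (max_iter <= 0) max_iter = std::max(10000000 / std::max(n, 1), 100 * n);

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  const double tau = 1e-12;

  int iter = 0;
  double gap = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    double gmax = -R_PosInf, gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double ygt = -y[t] * G[t];
      const bool in_up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool in_low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up && ygt > gmax) { gmax = ygt; i = t; }
      if (in_low && ygt < gmin) { gmin = ygt; j = t; }
    }
    gap = gmax - gmin;
    if (i < 0 || j < 0 || gap < tol) break;

    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    const double old_ai = alpha[i], old_aj = alpha[j];

    // pair curvature Q_ii + Q_jj - 2 Q_ij = K_ii + K_jj - 2 K_ij (any labels)
    const double quad0 = Kii + Kjj - 2.0 * Kij;
    if (y[i] != y[j]) {
      double quad = quad0;
      if (quad <= 0) quad = tau;
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
      double quad = quad0;
      if (quad <= 0) quad = tau;
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

    const double dai = y[i] * (alpha[i] - old_ai);
    const double daj = y[j] * (alpha[j] - old_aj);
    if (dai != 0.0 || daj != 0.0) {
      const double* ki = &K(0, i);
      const double* kj = &K(0, j);
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (ki[t] * dai + kj[t] * daj);
    }
  }

  // bias from the free support vectors (fall back to the violating bounds)
  double rho;
  {
    double sum = 0.0; int nfree = 0;
    double ub = R_PosInf, lb = -R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double ygt = y[t] * G[t];
      const bool upper = alpha[t] >= C, lower = alpha[t] <= 0;
      if (!upper && !lower) { sum += ygt; ++nfree; }
      else if ((y[t] == 1 && upper) || (y[t] == -1 && lower)) {
        if (ygt > lb) lb = ygt;
      } else {
        if (ygt < ub) ub = ygt;
      }
    }
    rho = nfree > 0 ? sum / nfree : (ub + lb) / 2.0;
  }

  NumericVector a(alpha.begin(), alpha.end());
  return List::create(_["alpha"] = a, _["rho"] = rho,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["converged"] = gap < tol);
}
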
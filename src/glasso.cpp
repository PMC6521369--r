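#include <Rcpp.h>
using namespace Rcpp;

// Block coordinate descent for the L1-penalised Gaussian log-likelihood
// (graphical lasso), penalising off-diagonal precision entries only.
// Each column's subproblem  min_b 1/2 b'W11 b - s12'b + rho*||b||_1
// is solved by coordinate descent with soft-thresholding; the working
// covariance estimate W is updated in place column by column.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix S, double rho,
               Nullable<NumericMatrix> W0, Nullable<NumericMatrix> B0,
               int max_iter, double tol,
               int inner_max_iter, double inner_tol) {
  const int p = S.nrow();
  if (S.ncol() != p) stop("S must be square");

  NumericMatrix W = W0.isNotNull() ? clone(as<NumericMatrix>(W0)) : clone(S);
  NumericMatrix B(p, p);
  if (B0.isNotNull()) B = clone(as<NumericMatrix>(B0));
  // diagonal is unpenalised: w_ii = s_ii at the optimum
  for (int i = 0; i < p; ++i) W(i, i) = S(i, i);

  double off_mean = 0.0;
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (i != j) off_mean += std::fabs(S(i, j));
  off_mean = (p > 1) ? off_mean / (double)(p * (p - 1)) : 0.0;
  const double thr = tol * std::max(off_mean, 1e-12);

  std::vector<double> b(p), cw(p);
  bool converged = (p == 1);
  int iter = 0;

  for (iter = 0; iter < max_iter && !converged; ++iter) {
    double dW = 0.0;
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < p; ++k) b[k] = B(k, j);
      b[j] = 0.0;
      // cw = W %*% b, maintained incrementally below
      for (int k = 0; k < p; ++k) cw[k] = 0.0;
      for (int l = 0; l < p; ++l) {
        const double bl = b[l];
        if (bl != 0.0) {
          const double* wl = &W(0, l);
          for (int k = 0; k < p; ++k) cw[k] += wl[k] * bl;
        }
      }
      for (int pass = 0; pass < inner_max_iter; ++pass) {
        double dmax = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          const double wkk = W(k, k);
          const double a = S(k, j) - (cw[k] - wkk * b[k]);
          const double bn = soft(a, rho) / wkk;
          const double db = bn - b[k];
          if (db != 0.0) {
            const double* wk = &W(0, k);
            for (int l = 0; l < p; ++l) cw[l] += wk[l] * db;
            b[k] = bn;
            const double adb = std::fabs(db);
            if (adb > dmax) dmax = adb;
          }
        }
        if (dmax < inner_tol) break;
      }
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        dW += std::fabs(cw[k] - W(k, j));
        W(k, j) = cw[k];
        W(j, k) = cw[k];
        B(k, j) = b[k];
      }
      B(j, j) = 0.0;
    }
    if (p > 1 && dW / (double)(p * (p - 1)) < thr) converged = true;
  }

  // recover the precision matrix from W and the regression coefficients
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k)
      if (k != j) dot += W(k, j) * B(k, j);
    const double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // symmetrise, keeping exact zeros where both triangles agree on zero
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < j; ++i) {
      const double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["theta"] = Theta, _["w"] = W, _["b"] = B,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
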
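#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman-Hastie-Tibshirani
// scheme): each column's off-diagonal block is updated by solving an
// L1-penalized quadratic program with cyclic coordinate descent and
// soft-thresholding. The diagonal of the precision matrix is unpenalized,
// so diag(W) stays at diag(S). Soft-thresholding produces exact zeros in
// the precision matrix.
//
// Maximizes  log det(Theta) - tr(S Theta) - lam * sum_{i != j} |Theta_ij|.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, double lam, double tol = 1e-6,
                int maxit = 500) {
  int p = S.nrow();
  if (S.ncol() != p) stop("S must be square");
  if (lam < 0) stop("lam must be nonnegative");

  NumericMatrix W(clone(S));        // working covariance estimate
  NumericMatrix B(p, p);            // B(k, j): beta_k for column j (B(j,j)=0)
  double inner_tol = std::min(tol, 1e-7);
  int sweeps = 0;
  bool converged = false;

  for (sweeps = 0; sweeps < maxit; sweeps++) {
    double dmax = 0.0;
    for (int j = 0; j < p; j++) {
      // coordinate descent on beta (length p, slot j unused/zero):
      // minimize 0.5 b' W11 b - s12' b + lam ||b||_1,  W11 = W[-j,-j]
      for (int inner = 0; inner < 1000; inner++) {
        double dbmax = 0.0;
        for (int k = 0; k < p; k++) {
          if (k == j) continue;
          double g = S(k, j);
          for (int l = 0; l < p; l++) {
            if (l == j || l == k) continue;
            g -= W(k, l) * B(l, j);
          }
          double bnew = soft(g, lam) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > dbmax) dbmax = d;
          B(k, j) = bnew;
        }
        if (dbmax < inner_tol) break;
      }
      // w12 <- W11 beta
      for (int k = 0; k < p; k++) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; l++) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (dmax < tol) { converged = true; sweeps++; break; }
  }

  // Recover Theta from W and B: theta_jj = 1/(w_jj - w12' beta),
  // theta_12 = -beta * theta_jj. Exact zeros in beta give exact zeros in
  // Theta; symmetry enforced by requiring both directions nonzero.
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; j++) {
    double q = W(j, j);
    for (int k = 0; k < p; k++)
      if (k != j) q -= W(k, j) * B(k, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; k++)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  for (int j = 0; j < p; j++) {
    for (int k = j + 1; k < p; k++) {
      if (Theta(k, j) == 0.0 || Theta(j, k) == 0.0) {
        Theta(k, j) = Theta(j, k) = 0.0;
      } else {
        double m = (Theta(k, j) + Theta(j, k)) / 2.0;
        Theta(k, j) = Theta(j, k) = m;
      }
    }
  }
  return List::create(_["Theta"] = Theta, _["W"] = W, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
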
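#include <Rcpp.h>
using namespace Rcpp;

// Graphical LASSO by block coordinate descent over columns, with a lasso
// (coordinate-descent) inner solve per column. Off-diagonals are penalized;
// the diagonal of the covariance estimate stays at the sample diagonal.
// Returns the penalized covariance W, the precision Theta, and convergence
// diagnostics. For rho = 0 this reduces to W = S (when S is invertible).

static double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix Sin, double rho, int max_iter = 100,
                double tol = 1e-4, int inner_max = 200,
                double inner_tol = 1e-7) {
  int p = Sin.nrow();
  NumericMatrix S(clone(Sin));
  NumericMatrix W(clone(Sin));
  NumericMatrix B(p, p); // B(k, j): lasso coefficients for column j

  // mean absolute off-diagonal of S sets the convergence scale
  double s_off = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) s_off += std::fabs(S(i, j));
  s_off /= std::max(1, p * (p - 1));
  double thresh = tol * std::max(s_off, 1e-12);

  int iter = 0;
  bool converged = (p == 1);
  std::vector<int> idx(p - 1);

  for (iter = 0; iter < max_iter && !converged; ++iter) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx[m++] = k;
      // lasso: min 0.5 b' W11 b - b' s12 + rho |b|_1
      std::vector<double> b(p - 1);
      for (int k = 0; k < p - 1; ++k) b[k] = B(idx[k], j);
      for (int in = 0; in < inner_max; ++in) {
        double del = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double grad = S(idx[k], j);
          for (int l = 0; l < p - 1; ++l)
            if (l != k) grad -= W(idx[k], idx[l]) * b[l];
          double denom = W(idx[k], idx[k]);
          double bnew = denom > 0 ? soft(grad, rho) / denom : 0.0;
          del = std::max(del, std::fabs(bnew - b[k]));
          b[k] = bnew;
        }
        if (del < inner_tol) break;
      }
      for (int k = 0; k < p - 1; ++k) {
        double w = 0.0;
        for (int l = 0; l < p - 1; ++l) w += W(idx[k], idx[l]) * b[l];
        max_change = std::max(max_change, std::fabs(W(idx[k], j) - w));
        W(idx[k], j) = w;
        W(j, idx[k]) = w;
        B(idx[k], j) = b[k];
      }
    }
    if (max_change < thresh) converged = true;
  }

  // recover Theta from the final (W, B)
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k)
      if (k != j) q -= W(k, j) * B(k, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // symmetrize (numerically asymmetric off-diagonals)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["w"] = W, _["theta"] = Theta,
                      _["iterations"] = iter, _["converged"] = converged);
}
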
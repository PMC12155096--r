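#include <Rcpp.h>
using namespace Rcpp;

// Best-matching unit (1-based) of each row of X against the codebook.
// [[Rcpp::export]]
IntegerVector som_bmu_cpp(NumericMatrix X, NumericMatrix W) {
  int n = X.nrow(), m = W.nrow(), d = X.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bd = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double df = W(j, k) - X(i, k);
        s += df * df;
      }
      if (s < bd) { bd = s; best = j; }
    }
    out[i] = best + 1;
  }
  return out;
}

// Online SOM training. `order` holds 0-based sample indices, one per update
// step; learning rate and neighborhood radius decay geometrically from
// (lr0, r0) to (lr1, r1) over the steps. cellx/celly are the hexagonal grid
// coordinates of the codebook cells; updates use a Gaussian neighborhood on
// those coordinates, truncated at 3 radii. No RNG is used here: determinism
// comes from the caller-supplied order.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, NumericMatrix W0,
                            NumericVector cellx, NumericVector celly,
                            IntegerVector order,
                            double lr0, double lr1,
                            double r0, double r1) {
  int m = W0.nrow(), d = W0.ncol();
  long T = order.size();
  NumericMatrix W = clone(W0);
  for (long t = 0; t < T; ++t) {
    double frac = (T <= 1) ? 0.0 : (double)t / (double)(T - 1);
    double lr = lr0 * std::pow(lr1 / lr0, frac);
    double sg = r0 * std::pow(r1 / r0, frac);
    int i = order[t];
    int best = 0;
    double bd = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double df = W(j, k) - X(i, k);
        s += df * df;
      }
      if (s < bd) { bd = s; best = j; }
    }
    double bx = cellx[best], by = celly[best];
    double cut = 9.0 * sg * sg;
    for (int j = 0; j < m; ++j) {
      double dx = cellx[j] - bx, dy = celly[j] - by;
      double g2 = dx * dx + dy * dy;
      if (g2 > cut) continue;
      double h = lr * std::exp(-g2 / (2.0 * sg * sg));
      for (int k = 0; k < d; ++k)
        W(j, k) += h * (X(i, k) - W(j, k));
    }
  }
  return W;
}
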
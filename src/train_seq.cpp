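#include <Rcpp.h>
using namespace Rcpp;

// Sequential (online) SOM weight updates.
//
// codebook: m x p (modified copy returned), data: n x p,
// order: 0-based data row index per step, eta/sigma: per-step schedules,
// griddist: m x m lattice distances, kind: 0 gaussian, 1 bubble,
// 2 cutgauss, 3 epanechnikov.
//
// Winner search breaks ties by the lowest neuron index; sigma == 0 degrades
// every kernel to the winner-only indicator.
// [[Rcpp::export(name = ".cpp_train_seq")]]
NumericMatrix cpp_train_seq(NumericMatrix codebook, NumericMatrix data,
                            IntegerVector order, NumericVector eta,
                            NumericVector sigma, NumericMatrix griddist,
                            int kind) {
  const int m = codebook.nrow(), p = codebook.ncol();
  NumericMatrix w = clone(codebook);
  const int steps = order.size();
  for (int s = 0; s < steps; ++s) {
    const int r = order[s];
    // winner: minimal squared Euclidean distance, lowest index on ties
    int win = 0;
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (int q = 0; q < p; ++q) {
        const double diff = w(j, q) - data(r, q);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; win = j; }
    }
    const double sg = sigma[s], et = eta[s];
    for (int j = 0; j < m; ++j) {
      const double d = griddist(j, win);
      double h;
      if (sg <= 0.0) {
        h = (d == 0.0) ? 1.0 : 0.0;
      } else if (kind == 0) {            // gaussian
        h = std::exp(-(d * d) / (2.0 * sg * sg));
      } else if (kind == 1) {            // bubble
        h = (d <= sg) ? 1.0 : 0.0;
      } else if (kind == 2) {            // cut gaussian
        h = (d <= sg) ? std::exp(-(d * d) / (2.0 * sg * sg)) : 0.0;
      } else {                           // epanechnikov
        const double u = d / sg;
        h = 1.0 - u * u;
        if (h < 0.0) h = 0.0;
      }
      if (h == 0.0) continue;
      const double a = et * h;
      for (int q = 0; q < p; ++q) {
        w(j, q) += a * (data(r, q) - w(j, q));
      }
    }
  }
  return w;
}
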
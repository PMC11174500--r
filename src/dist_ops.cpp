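#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - pts(j, 0), dy = yi - pts(j, 1), dz = zi - pts(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// For each row of a, the distance to the nearest row of b (ADD-S inner scan).
// [[Rcpp::export(name = ".cpp_nn_dists")]]
NumericVector cpp_nn_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = xi - b(j, 0), dy = yi - b(j, 1), dz = zi - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
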
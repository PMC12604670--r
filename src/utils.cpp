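#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each query point to a set of reference
// points (boundary pixels). Exact O(n*m) scan, no acceleration structure:
// problem sizes are ~1e4 x ~1e3.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericVector px, NumericVector py,
                           NumericVector bx, NumericVector by) {
  const int n = px.size(), m = bx.size();
  if (m == 0) stop("empty reference point set");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = px[i], y = py[i];
    for (int j = 0; j < m; ++j) {
      const double dx = x - bx[j], dy = y - by[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
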
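// 2D Delaunay triangulation by Bowyer-Watson incremental insertion.
// Sizes here are a few hundred points (minicircle centres of mass), so the
// O(n^2) scan over triangles is fine and robustness is handled with a
// scaled epsilon in the in-circumcircle test.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Tri { int a, b, c; };

inline bool incircle(double ax, double ay, double bx, double by,
                     double cx, double cy, double px, double py,
                     double eps) {
  // assumes (a, b, c) counterclockwise; > 0 when p inside circumcircle
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy) -
               ady * (bdx * cd - bd * cdx) +
               ad * (bdx * cdy - bdy * cdx);
  return det > eps;
}

inline double orient(double ax, double ay, double bx, double by,
                     double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector px, NumericVector py) {
  const int n = px.size();
  if (n < 3) stop("need >= 3 points");
  std::vector<double> X(px.begin(), px.end()), Y(py.begin(), py.end());
  double xmin = X[0], xmax = X[0], ymin = Y[0], ymax = Y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, X[i]); xmax = std::max(xmax, X[i]);
    ymin = std::min(ymin, Y[i]); ymax = std::max(ymax, Y[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) stop("degenerate (coincident) point set");
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  // super-triangle vertices appended at indices n, n+1, n+2
  X.push_back(cx - 30.0 * dmax); Y.push_back(cy - 10.0 * dmax);
  X.push_back(cx + 30.0 * dmax); Y.push_back(cy - 10.0 * dmax);
  X.push_back(cx);               Y.push_back(cy + 30.0 * dmax);
  const double eps = 1e-12 * dmax * dmax * dmax * dmax;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2});

  std::vector<std::pair<int, int> > poly;
  std::vector<char> bad;
  for (int p = 0; p < n; ++p) {
    bad.assign(tris.size(), 0);
    poly.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      const Tri& T = tris[t];
      if (incircle(X[T.a], Y[T.a], X[T.b], Y[T.b], X[T.c], Y[T.c],
                   X[p], Y[p], eps))
        bad[t] = 1;
    }
    // boundary of the union of bad triangles
    auto add_edge = [&](int u, int v) {
      for (size_t e = 0; e < poly.size(); ++e) {
        if (poly[e].first == v && poly[e].second == u) {
          poly.erase(poly.begin() + e);
          return;
        }
      }
      poly.push_back(std::make_pair(u, v));
    };
    std::vector<Tri> keep;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (bad[t]) {
        add_edge(tris[t].a, tris[t].b);
        add_edge(tris[t].b, tris[t].c);
        add_edge(tris[t].c, tris[t].a);
      } else {
        keep.push_back(tris[t]);
      }
    }
    tris.swap(keep);
    for (size_t e = 0; e < poly.size(); ++e) {
      Tri T = {poly[e].first, poly[e].second, p};
      // enforce counterclockwise orientation
      if (orient(X[T.a], Y[T.a], X[T.b], Y[T.b], X[T.c], Y[T.c]) < 0)
        std::swap(T.b, T.c);
      tris.push_back(T);
    }
  }
  std::vector<Tri> out;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri& T = tris[t];
    if (T.a < n && T.b < n && T.c < n) out.push_back(T);
  }
  if (out.empty()) stop("triangulation failed (collinear point set?)");
  IntegerMatrix res((int)out.size(), 3);
  for (size_t t = 0; t < out.size(); ++t) {
    res(t, 0) = out[t].a + 1;
    res(t, 1) = out[t].b + 1;
    res(t, 2) = out[t].c + 1;
  }
  return res;
}
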
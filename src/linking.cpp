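#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gauss linking number of two closed polylines via the exact segment-pair
// solid-angle formula (Klenin & Langowski 2000, method 1a; after
// Banchoff/Arai). For segments p1->p2 and p3->p4 the contribution is the
// signed solid angle of the quadrilateral spanned by the endpoint
// directions, and Lk = sum / (4 pi).

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// signed solid angle contribution of one segment pair; *degenerate set to
// true when the configuration is numerically singular
static double seg_pair_omega(const double* p1, const double* p2,
                             const double* p3, const double* p4,
                             bool* degenerate) {
  double r13[3], r14[3], r23[3], r24[3], r34[3], r12[3];
  for (int k = 0; k < 3; ++k) {
    r13[k] = p3[k] - p1[k];
    r14[k] = p4[k] - p1[k];
    r23[k] = p3[k] - p2[k];
    r24[k] = p4[k] - p2[k];
    r34[k] = p4[k] - p3[k];
    r12[k] = p2[k] - p1[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  const double eps = 1e-14;
  double l1 = std::sqrt(dot3(n1, n1)), l2 = std::sqrt(dot3(n2, n2));
  double l3 = std::sqrt(dot3(n3, n3)), l4 = std::sqrt(dot3(n4, n4));
  if (l1 < eps || l2 < eps || l3 < eps || l4 < eps) {
    // coplanar or touching segment pair: solid angle 0 unless truly
    // intersecting, which we flag
    double c[3];
    cross3(r34, r12, c);
    if (std::sqrt(dot3(c, c)) < eps) return 0.0;  // parallel: no solid angle
    *degenerate = true;
    return 0.0;
  }
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }
  double omega = std::asin(clamp1(dot3(n1, n2))) +
                 std::asin(clamp1(dot3(n2, n3))) +
                 std::asin(clamp1(dot3(n3, n4))) +
                 std::asin(clamp1(dot3(n4, n1)));
  double c[3];
  cross3(r34, r12, c);
  double s = dot3(c, r13);
  return (s > 0) - (s < 0) ? omega * ((s > 0) ? 1.0 : -1.0) : 0.0;
}

// [[Rcpp::export]]
List cpp_linking_number(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  if (na < 3 || nb < 3) stop("rings need >= 3 vertices");
  std::vector<double> A(3 * (na + 1)), B(3 * (nb + 1));
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) A[3 * i + k] = a(i, k);
  for (int k = 0; k < 3; ++k) A[3 * na + k] = a(0, k);
  for (int i = 0; i < nb; ++i)
    for (int k = 0; k < 3; ++k) B[3 * i + k] = b(i, k);
  for (int k = 0; k < 3; ++k) B[3 * nb + k] = b(0, k);
  double total = 0.0;
  bool degen = false;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      total += seg_pair_omega(&A[3 * i], &A[3 * (i + 1)],
                              &B[3 * j], &B[3 * (j + 1)], &degen);
    }
  }
  double lk = total / (4.0 * M_PI);
  return List::create(_["lk"] = lk, _["degenerate"] = degen);
}

// Full linking matrix for a set of rings supplied as one coordinate matrix
// plus ring lengths. Ring pairs whose bounding spheres are disjoint are
// rigorously unlinked and skipped.
// [[Rcpp::export]]
IntegerMatrix cpp_link_matrix(NumericMatrix pos, IntegerVector ring_len,
                              double tol) {
  const int nr = ring_len.size();
  std::vector<int> offset(nr + 1, 0);
  for (int r = 0; r < nr; ++r) offset[r + 1] = offset[r] + ring_len[r];
  if (offset[nr] != pos.nrow()) stop("ring lengths do not match positions");
  // centres and radii for the sphere prefilter
  std::vector<double> cx(nr), cy(nr), cz(nr), rad(nr, 0.0);
  for (int r = 0; r < nr; ++r) {
    double sx = 0, sy = 0, sz = 0;
    for (int i = offset[r]; i < offset[r + 1]; ++i) {
      sx += pos(i, 0); sy += pos(i, 1); sz += pos(i, 2);
    }
    const int m = ring_len[r];
    cx[r] = sx / m; cy[r] = sy / m; cz[r] = sz / m;
    for (int i = offset[r]; i < offset[r + 1]; ++i) {
      double dx = pos(i, 0) - cx[r], dy = pos(i, 1) - cy[r],
             dz = pos(i, 2) - cz[r];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rad[r]) rad[r] = d;
    }
  }
  IntegerMatrix lk(nr, nr);
  for (int r = 0; r < nr; ++r) {
    for (int s = r + 1; s < nr; ++s) {
      double dx = cx[r] - cx[s], dy = cy[r] - cy[s], dz = cz[r] - cz[s];
      double cdist = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (cdist > rad[r] + rad[s] + 0.5) continue;  // disjoint spheres
      double total = 0.0;
      bool degen = false;
      const int ma = ring_len[r], mb = ring_len[s];
      const int oa = offset[r], ob = offset[s];
      for (int i = 0; i < ma; ++i) {
        const int i2 = (i + 1) % ma;
        double p1[3] = {pos(oa + i, 0), pos(oa + i, 1), pos(oa + i, 2)};
        double p2[3] = {pos(oa + i2, 0), pos(oa + i2, 1), pos(oa + i2, 2)};
        for (int j = 0; j < mb; ++j) {
          const int j2 = (j + 1) % mb;
          double p3[3] = {pos(ob + j, 0), pos(ob + j, 1), pos(ob + j, 2)};
          double p4[3] = {pos(ob + j2, 0), pos(ob + j2, 1), pos(ob + j2, 2)};
          total += seg_pair_omega(p1, p2, p3, p4, &degen);
        }
      }
      double v = total / (4.0 * M_PI);
      int iv = (int)std::lround(v);
      if (degen || std::fabs(v - iv) > tol)
        stop("linking number %f for ring pair (%d, %d) is not close to an "
             "integer (tol %f); segments may touch", v, r + 1, s + 1, tol);
      lk(r, s) = iv;
      lk(s, r) = iv;
    }
  }
  return lk;
}
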
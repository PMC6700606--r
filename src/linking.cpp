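#include "models.h"

using namespace Rcpp;

namespace {

// Analytic Gauss integral of one straight segment pair: the contribution
// equals the signed solid angle of the spherical quadrilateral spanned by
// the four normalized endpoint-difference vectors, divided by 4*pi
// (Klenin & Langowski, Biopolymers 54:307). The quadrilateral area is
// evaluated as two spherical triangles with the van Oosterom-Strackee
// atan2 formula, which is accurate for all dihedral configurations where
// the asin variant loses precision.
double segment_pair_gauss(const double* p1, const double* p2, const double* p3,
                          const double* p4) {
  double a[3], b[3], c[3], d[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = p3[k] - p1[k];
    b[k] = p4[k] - p1[k];
    c[k] = p4[k] - p2[k];
    d[k] = p3[k] - p2[k];
  }
  double la = lf::norm3(a), lb = lf::norm3(b), lc = lf::norm3(c),
         ld = lf::norm3(d);
  if (la < 1e-14 || lb < 1e-14 || lc < 1e-14 || ld < 1e-14) return 0.0;
  for (int k = 0; k < 3; ++k) {
    a[k] /= la;
    b[k] /= lb;
    c[k] /= lc;
    d[k] /= ld;
  }
  auto solid = [](const double* u, const double* v, const double* w) {
    double cr[3];
    lf::cross3(v, w, cr);
    double num = lf::dot3(u, cr);
    double den = 1.0 + lf::dot3(u, v) + lf::dot3(v, w) + lf::dot3(w, u);
    return 2.0 * std::atan2(num, den);
  };
  double omega = solid(a, b, c) + solid(a, c, d);
  if (omega > 2.0 * M_PI) omega -= 4.0 * M_PI;
  if (omega < -2.0 * M_PI) omega += 4.0 * M_PI;
  return -omega / (4.0 * M_PI);
}

}  // namespace

// Gauss linking number of two open (or closed) polygonal curves, as the sum
// of exact analytic segment-pair integrals. Curves are M x 3 vertex
// matrices traversed in row order. Vertices of one curve coinciding with
// vertices of the other are perturbed by 1e-9 to regularize the integrand.
// [[Rcpp::export]]
double gauss_linking_cpp(NumericMatrix curve1, NumericMatrix curve2) {
  int m1 = curve1.nrow(), m2 = curve2.nrow();
  if (m1 < 2 || m2 < 2) stop("each curve needs at least 2 vertices");
  std::vector<double> a(3 * m1), b(3 * m2);
  for (int i = 0; i < m1; ++i)
    for (int c = 0; c < 3; ++c) a[3 * i + c] = curve1(i, c);
  for (int j = 0; j < m2; ++j)
    for (int c = 0; c < 3; ++c) b[3 * j + c] = curve2(j, c);
  bool warned = false;
  for (int i = 0; i < m1; ++i) {
    for (int j = 0; j < m2; ++j) {
      double d[3] = {a[3 * i] - b[3 * j], a[3 * i + 1] - b[3 * j + 1],
                     a[3 * i + 2] - b[3 * j + 2]};
      if (lf::dot3(d, d) < 1e-24) {
        b[3 * j] += 1e-9;
        b[3 * j + 1] += 1e-9;
        if (!warned) {
          Rf_warning("coincident vertices across curves; regularized with 1e-9 offset");
          warned = true;
        }
      }
    }
  }
  double G = 0.0;
  for (int i = 0; i + 1 < m1; ++i)
    for (int j = 0; j + 1 < m2; ++j)
      G += segment_pair_gauss(&a[3 * i], &a[3 * (i + 1)], &b[3 * j],
                              &b[3 * (j + 1)]);
  return G;
}

// [[Rcpp::export]]
double segment_pair_gauss_cpp(NumericVector p1, NumericVector p2,
                              NumericVector p3, NumericVector p4) {
  return segment_pair_gauss(p1.begin(), p2.begin(), p3.begin(), p4.begin());
}
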
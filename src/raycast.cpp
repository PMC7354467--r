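#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Ray casting (Moller-Trumbore) and point-to-triangle distance against a
// triangle soup. Brute force over triangles: strain projection works on a
// single subject pair at a time, where K_triangles * N_points stays small
// enough that the simple kernel is faster than building acceleration
// structures would pay for.

namespace {

inline void tri_vertices(const NumericMatrix &V, const IntegerMatrix &F, int k,
                         double *a, double *b, double *c) {
  int ia = F(k, 0) - 1, ib = F(k, 1) - 1, ic = F(k, 2) - 1;
  for (int j = 0; j < 3; ++j) {
    a[j] = V(ia, j); b[j] = V(ib, j); c[j] = V(ic, j);
  }
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
inline double point_tri_d2(const double *p, const double *a, const double *b,
                           const double *c) {
  double ab[3], ac[3], ap[3];
  for (int j = 0; j < 3; ++j) { ab[j] = b[j] - a[j]; ac[j] = c[j] - a[j]; ap[j] = p[j] - a[j]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; }
  else {
    double bp[3]; for (int j = 0; j < 3; ++j) bp[j] = p[j] - b[j];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int j = 0; j < 3; ++j) q[j] = a[j] + v * ab[j];
      } else {
        double cp[3]; for (int j = 0; j < 3; ++j) cp[j] = p[j] - c[j];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int j = 0; j < 3; ++j) q[j] = a[j] + w * ac[j];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int j = 0; j < 3; ++j) q[j] = b[j] + w * (c[j] - b[j]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int j = 0; j < 3; ++j) q[j] = a[j] + ab[j] * v + ac[j] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

} // namespace

// First positive ray/mesh intersection distance along each (origin, dir).
// Returns NA where no hit within cutoff. dirs need not be unit length; the
// returned t is a Euclidean distance (dirs are normalised internally).
// [[Rcpp::export(name = ".cpp_ray_mesh")]]
NumericVector cpp_ray_mesh(NumericMatrix origins, NumericMatrix dirs,
                           NumericMatrix V, IntegerMatrix F, double cutoff) {
  const double EPS = 1e-12;
  int n = origins.nrow(), K = F.nrow();
  NumericVector out(n, NA_REAL);

  // Precompute triangle vertices + edges once.
  std::vector<double> A(3 * K), E1(3 * K), E2(3 * K);
  for (int k = 0; k < K; ++k) {
    double a[3], b[3], c[3];
    tri_vertices(V, F, k, a, b, c);
    for (int j = 0; j < 3; ++j) {
      A[3*k+j]  = a[j];
      E1[3*k+j] = b[j] - a[j];
      E2[3*k+j] = c[j] - a[j];
    }
  }

  for (int i = 0; i < n; ++i) {
    double o[3] = { origins(i,0), origins(i,1), origins(i,2) };
    double d[3] = { dirs(i,0), dirs(i,1), dirs(i,2) };
    double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (nrm < EPS) continue;
    for (int j = 0; j < 3; ++j) d[j] /= nrm;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      const double *a = &A[3*k], *e1 = &E1[3*k], *e2 = &E2[3*k];
      double h[3] = { d[1]*e2[2]-d[2]*e2[1], d[2]*e2[0]-d[0]*e2[2], d[0]*e2[1]-d[1]*e2[0] };
      double det = e1[0]*h[0] + e1[1]*h[1] + e1[2]*h[2];
      if (std::fabs(det) < EPS) continue;
      double inv = 1.0 / det;
      double s[3] = { o[0]-a[0], o[1]-a[1], o[2]-a[2] };
      double u = (s[0]*h[0] + s[1]*h[1] + s[2]*h[2]) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qv[3] = { s[1]*e1[2]-s[2]*e1[1], s[2]*e1[0]-s[0]*e1[2], s[0]*e1[1]-s[1]*e1[0] };
      double v = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
      if (t > 1e-9 && t < best) best = t;
    }
    if (best <= cutoff) out[i] = best;
  }
  return out;
}

// Unsigned distance from each point to the nearest point of the mesh surface.
// [[Rcpp::export(name = ".cpp_point_mesh_dist")]]
NumericVector cpp_point_mesh_dist(NumericMatrix points, NumericMatrix V,
                                  IntegerMatrix F) {
  int n = points.nrow(), K = F.nrow();
  NumericVector out(n);
  std::vector<double> tri(9 * K);
  for (int k = 0; k < K; ++k)
    tri_vertices(V, F, k, &tri[9*k], &tri[9*k+3], &tri[9*k+6]);
  for (int i = 0; i < n; ++i) {
    double p[3] = { points(i,0), points(i,1), points(i,2) };
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double d2 = point_tri_d2(p, &tri[9*k], &tri[9*k+3], &tri[9*k+6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
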
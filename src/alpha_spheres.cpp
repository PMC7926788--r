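#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Enumerate alpha spheres: every 4-atom combination whose circumsphere has
// radius in [rmin, rmax] and contains no atom center strictly inside
// (distance < radius - inside_tol). In general position these are exactly
// the Delaunay tetrahedra with circumradius in the band, since an empty
// circumsphere certifies Delaunay membership. Pairwise pruning at 2*rmax
// (four points on a sphere of radius r are pairwise within 2r) keeps the
// quadruple loop tractable.
//
// coords: n x 3 matrix. Returns a matrix with columns
// i1,i2,i3,i4 (1-based), cx, cy, cz, radius.
// [[Rcpp::export]]
NumericMatrix cpp_alpha_spheres(NumericMatrix coords, double rmin, double rmax,
                                double inside_tol, double vol_tol) {
  int n = coords.nrow();
  if (n < 4) stop("need at least 4 atoms");
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = coords(i, 0);
    P[3 * i + 1] = coords(i, 1);
    P[3 * i + 2] = coords(i, 2);
  }
  double D = 2.0 * rmax, D2 = D * D;
  auto d2 = [&](int a, int b) {
    double dx = P[3 * a] - P[3 * b], dy = P[3 * a + 1] - P[3 * b + 1],
           dz = P[3 * a + 2] - P[3 * b + 2];
    return dx * dx + dy * dy + dz * dz;
  };
  std::vector<double> out;  // rows of 8
  // neighbor lists under the 2*rmax cutoff (four points on a sphere of
  // radius <= rmax are pairwise within 2*rmax)
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (d2(i, j) <= D2) nb[i].push_back(j);
  // Work in coordinates relative to atom i: with q = p - p_i the
  // circumcentre c' (relative) solves 2 q_m . c' = |q_m|^2 for m = j,k,l,
  // so by Cramer  c' = (|q_j|^2 (q_k x q_l) + |q_k|^2 (q_l x q_j)
  //                     + |q_l|^2 (q_j x q_k)) / (2 q_j . (q_k x q_l))
  // and radius = |c'|. q_j x q_k is reused across the l loop.
  std::vector<double> QX, QY, QZ, QN;
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &Ni = nb[i];
    size_t m = Ni.size();
    if (m < 3) continue;
    QX.resize(m); QY.resize(m); QZ.resize(m); QN.resize(m);
    for (size_t a = 0; a < m; ++a) {
      int j = Ni[a];
      QX[a] = P[3 * j] - P[3 * i];
      QY[a] = P[3 * j + 1] - P[3 * i + 1];
      QZ[a] = P[3 * j + 2] - P[3 * i + 2];
      QN[a] = QX[a] * QX[a] + QY[a] * QY[a] + QZ[a] * QZ[a];
    }
    for (size_t a = 0; a < m; ++a) {
      int j = Ni[a];
      for (size_t b = a + 1; b < m; ++b) {
        int k = Ni[b];
        if (d2(j, k) > D2) continue;
        // q_j x q_k, constant over l
        double cjk_x = QY[a] * QZ[b] - QZ[a] * QY[b];
        double cjk_y = QZ[a] * QX[b] - QX[a] * QZ[b];
        double cjk_z = QX[a] * QY[b] - QY[a] * QX[b];
        for (size_t cc = b + 1; cc < m; ++cc) {
          int l = Ni[cc];
          if (d2(j, l) > D2 || d2(k, l) > D2) continue;
          double lx = QX[cc], ly = QY[cc], lz = QZ[cc];
          double det = cjk_x * lx + cjk_y * ly + cjk_z * lz;  // q_l.(qj x qk)
          // |det| = 6 * tetrahedron volume
          if (std::fabs(det) / 6.0 <= vol_tol) continue;
          double ckl_x = QY[b] * QZ[cc] - QZ[b] * QY[cc];
          double ckl_y = QZ[b] * QX[cc] - QX[b] * QZ[cc];
          double ckl_z = QX[b] * QY[cc] - QY[b] * QX[cc];
          double clj_x = QY[cc] * QZ[a] - QZ[cc] * QY[a];
          double clj_y = QZ[cc] * QX[a] - QX[cc] * QZ[a];
          double clj_z = QX[cc] * QY[a] - QY[cc] * QX[a];
          double inv = 0.5 / det;
          double cx = (QN[a] * ckl_x + QN[b] * clj_x + QN[cc] * cjk_x) * inv;
          double cy = (QN[a] * ckl_y + QN[b] * clj_y + QN[cc] * cjk_y) * inv;
          double cz = (QN[a] * ckl_z + QN[b] * clj_z + QN[cc] * cjk_z) * inv;
          double r2 = cx * cx + cy * cy + cz * cz;
          if (r2 < rmin * rmin || r2 > rmax * rmax) continue;
          double r = std::sqrt(r2);
          double gx = cx + P[3 * i], gy = cy + P[3 * i + 1],
                 gz = cz + P[3 * i + 2];
          bool empty = true;
          double rin = r - inside_tol;
          double rin2 = rin * rin;
          for (int q = 0; q < n; ++q) {
            double dx = P[3 * q] - gx, dy = P[3 * q + 1] - gy,
                   dz = P[3 * q + 2] - gz;
            if (dx * dx + dy * dy + dz * dz < rin2) {
              empty = false;
              break;
            }
          }
          if (!empty) continue;
          out.push_back(i + 1);
          out.push_back(j + 1);
          out.push_back(k + 1);
          out.push_back(l + 1);
          out.push_back(gx);
          out.push_back(gy);
          out.push_back(gz);
          out.push_back(r);
        }
      }
    }
  }
  int nr = (int)(out.size() / 8);
  NumericMatrix res(nr, 8);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 8; ++j) res(i, j) = out[8 * i + j];
  colnames(res) = CharacterVector::create("i1", "i2", "i3", "i4", "cx", "cy",
                                          "cz", "radius");
  return res;
}
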
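#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// First-hit ray casting against a triangle soup (Moller-Trumbore).
// One ray per source triangle: origin = its centroid, direction = its
// into-lumen normal. Triangles whose centroid lies within `exclusion_mm`
// of the ray origin are skipped so a ray cannot hit its own neighbourhood
// of the wall. Returns the hit distance in mm, or NA for rays that escape
// (e.g. through an aperture).
// [[Rcpp::export(name = ".raycast_first_hit")]]
NumericVector raycast_first_hit(NumericMatrix origins, NumericMatrix dirs,
                                NumericMatrix V, IntegerMatrix F,
                                NumericMatrix tri_centroids,
                                double exclusion_mm) {
  const int nray = origins.nrow();
  const int ntri = F.nrow();
  const double EPS = 1e-9;
  const double excl2 = exclusion_mm * exclusion_mm;
  NumericVector out(nray, NA_REAL);

  // unpack triangle vertices once
  std::vector<double> ax(ntri), ay(ntri), az(ntri);
  std::vector<double> e1x(ntri), e1y(ntri), e1z(ntri);
  std::vector<double> e2x(ntri), e2y(ntri), e2z(ntri);
  for (int t = 0; t < ntri; ++t) {
    int i0 = F(t, 0) - 1, i1 = F(t, 1) - 1, i2 = F(t, 2) - 1;
    ax[t] = V(i0, 0); ay[t] = V(i0, 1); az[t] = V(i0, 2);
    e1x[t] = V(i1, 0) - ax[t]; e1y[t] = V(i1, 1) - ay[t]; e1z[t] = V(i1, 2) - az[t];
    e2x[t] = V(i2, 0) - ax[t]; e2y[t] = V(i2, 1) - ay[t]; e2z[t] = V(i2, 2) - az[t];
  }

  for (int r = 0; r < nray; ++r) {
    const double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    const double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < ntri; ++t) {
      double cx = tri_centroids(t, 0) - ox;
      double cy = tri_centroids(t, 1) - oy;
      double cz = tri_centroids(t, 2) - oz;
      if (cx * cx + cy * cy + cz * cz <= excl2) continue;

      // Moller-Trumbore
      double px = dy * e2z[t] - dz * e2y[t];
      double py = dz * e2x[t] - dx * e2z[t];
      double pz = dx * e2y[t] - dy * e2x[t];
      double det = e1x[t] * px + e1y[t] * py + e1z[t] * pz;
      if (std::fabs(det) < EPS) continue;
      double inv = 1.0 / det;
      double tx = ox - ax[t], ty = oy - ay[t], tz = oz - az[t];
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qx = ty * e1z[t] - tz * e1y[t];
      double qy = tz * e1x[t] - tx * e1z[t];
      double qz = tx * e1y[t] - ty * e1x[t];
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double tt = (e2x[t] * qx + e2y[t] * qy + e2z[t] * qz) * inv;
      if (tt > EPS && tt < best) best = tt;
    }
    if (std::isfinite(best)) out[r] = best;
  }
  return out;
}
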
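#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the Kuhn 6-tetrahedron
// cube decomposition (all tets share the cube's main diagonal, so face
// diagonals match between neighbouring cubes and the surface is crack-free).
// Surface vertices are linearly interpolated along grid edges and shared via
// an edge hash, so the triangulation is vertex-welded. Triangles are wound
// so their right-hand normals point toward the side where field > level
// (for a cavity indicator field that is "into the lumen").

// Kuhn decomposition: corner bits are (x | y<<1 | z<<2).
static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

struct VKey {
  int64_t a, b;
  bool operator==(const VKey& o) const { return a == o.a && b == o.b; }
};
struct VKeyHash {
  size_t operator()(const VKey& k) const {
    return std::hash<int64_t>()(k.a * 1000003 + k.b);
  }
};

// [[Rcpp::export(name = ".march_tet")]]
List march_tet(NumericVector field, IntegerVector dims, double level,
               NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* F = REAL(field);
  auto lin = [&](int i, int j, int k) -> int64_t {
    return (int64_t)k * nx * ny + (int64_t)j * nx + i;
  };

  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<VKey, int, VKeyHash> edge_vertex;

  // world coordinates of grid node (i,j,k)
  auto wx = [&](int i) { return origin[0] + spacing[0] * i; };
  auto wy = [&](int j) { return origin[1] + spacing[1] * j; };
  auto wz = [&](int k) { return origin[2] + spacing[2] * k; };

  // vertex on edge between grid nodes g0 < g1, interpolation parameter t
  auto edge_point = [&](int64_t g0, int64_t g1, double f0, double f1,
                        int i0, int j0, int k0, int i1, int j1, int k1) -> int {
    VKey key;
    if (g0 < g1) { key.a = g0; key.b = g1; }
    else { key.a = g1; key.b = g0; std::swap(f0, f1);
           std::swap(i0, i1); std::swap(j0, j1); std::swap(k0, k1); }
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - f0) / (f1 - f0);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double px = wx(i0) + t * (wx(i1) - wx(i0));
    double py = wy(j0) + t * (wy(j1) - wy(j0));
    double pz = wz(k0) + t * (wz(k1) - wz(k0));
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vertex.emplace(key, id);
    return id;
  };

  int ci[8], cj[8], ck[8];
  int64_t cg[8];
  double cf[8];

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          ci[c] = i + (c & 1);
          cj[c] = j + ((c >> 1) & 1);
          ck[c] = k + ((c >> 2) & 1);
          cg[c] = lin(ci[c], cj[c], ck[c]);
          cf[c] = F[cg[c]];
          if (cf[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;

        for (int t = 0; t < 6; ++t) {
          int a = TETS[t][0], b = TETS[t][1], c = TETS[t][2], d = TETS[t][3];
          int corners[4] = {a, b, c, d};
          int pos[4], npos = 0, neg[4], nneg = 0;
          for (int m = 0; m < 4; ++m) {
            if (cf[corners[m]] > level) pos[npos++] = corners[m];
            else neg[nneg++] = corners[m];
          }
          if (npos == 0 || npos == 4) continue;

          auto EP = [&](int u, int v) {
            return edge_point(cg[u], cg[v], cf[u], cf[v],
                              ci[u], cj[u], ck[u], ci[v], cj[v], ck[v]);
          };
          // centroid of positive corners: reference for orientation
          double rx = 0, ry = 0, rz = 0;
          for (int m = 0; m < npos; ++m) {
            rx += wx(ci[pos[m]]); ry += wy(cj[pos[m]]); rz += wz(ck[pos[m]]);
          }
          rx /= npos; ry /= npos; rz /= npos;

          auto emit = [&](int p0, int p1, int p2) {
            if (p0 == p1 || p1 == p2 || p0 == p2) return; // degenerate
            // orient so the normal points toward the positive side
            double ax = vx[p1] - vx[p0], ay = vy[p1] - vy[p0], az = vz[p1] - vz[p0];
            double bx2 = vx[p2] - vx[p0], by2 = vy[p2] - vy[p0], bz2 = vz[p2] - vz[p0];
            double nxn = ay * bz2 - az * by2;
            double nyn = az * bx2 - ax * bz2;
            double nzn = ax * by2 - ay * bx2;
            double cx = (vx[p0] + vx[p1] + vx[p2]) / 3.0;
            double cy = (vy[p0] + vy[p1] + vy[p2]) / 3.0;
            double cz = (vz[p0] + vz[p1] + vz[p2]) / 3.0;
            double dot = nxn * (rx - cx) + nyn * (ry - cy) + nzn * (rz - cz);
            if (dot >= 0) {
              tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
            } else {
              tri.push_back(p0); tri.push_back(p2); tri.push_back(p1);
            }
          };

          if (npos == 1) {
            emit(EP(pos[0], neg[0]), EP(pos[0], neg[1]), EP(pos[0], neg[2]));
          } else if (npos == 3) {
            emit(EP(pos[0], neg[0]), EP(pos[1], neg[0]), EP(pos[2], neg[0]));
          } else { // 2-2: quad split into two triangles
            int q0 = EP(pos[0], neg[0]);
            int q1 = EP(pos[0], neg[1]);
            int q2 = EP(pos[1], neg[1]);
            int q3 = EP(pos[1], neg[0]);
            emit(q0, q1, q2);
            emit(q0, q2, q3);
          }
        }
      }
    }
  }

  int nvert = (int)vx.size();
  NumericMatrix V(nvert, 3);
  for (int m = 0; m < nvert; ++m) {
    V(m, 0) = vx[m]; V(m, 1) = vy[m]; V(m, 2) = vz[m];
  }
  int ntri = (int)tri.size() / 3;
  IntegerMatrix Fm(ntri, 3);
  for (int m = 0; m < ntri; ++m) {
    Fm(m, 0) = tri[3 * m] + 1;      // 1-based for R
    Fm(m, 1) = tri[3 * m + 1] + 1;
    Fm(m, 2) = tri[3 * m + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
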
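// 3D voxel / mesh primitives used across the pipeline.
// All arrays are R column-major: index = i + nx*(j + ny*k), 0-based here.
#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <functional>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double BIG = 1e30; // finite stand-in for "no feature in column"

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// anisotropic spacing in mm. Returns squared distance (mm^2) from each voxel
// centre to the nearest feature voxel centre.
// ---------------------------------------------------------------------------

// 1-D squared distance transform under sample spacing `step`. Values of BIG
// propagate columns with no feature; they stay >= BIG/2 and are mapped back
// to Inf at the end of the full transform.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double step) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
      if (k > 0 && s <= z[k]) { k--; continue; }
      break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = s2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = feature[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = D[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) D[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = D[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) D[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) f[k] = D[base + stride * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) D[base + stride * k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; i++)
    if (D[i] >= BIG / 2) D[i] = INF;
  return D;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (voxel units), truncated at 3 sigma.
// ---------------------------------------------------------------------------
static void conv1d(const std::vector<double>& in, std::vector<double>& out,
                   const std::vector<double>& ker, int n) {
  int r = ((int)ker.size() - 1) / 2;
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int t = -r; t <= r; t++) {
      int ii = i + t;
      if (ii < 0) ii = 0;
      if (ii >= n) ii = n - 1;
      s += in[ii] * ker[t + r];
    }
    out[i] = s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), res(nmax);
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int t = -r; t <= r; t++) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (auto& kv : ker) kv /= tot;
    if (ax == 0) {
      for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = 0; i < nx; i++) line[i] = out[base + i];
          conv1d(line, res, ker, nx);
          for (int i = 0; i < nx; i++) out[base + i] = res[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
          R_xlen_t base = i + (R_xlen_t)nx * ny * k;
          for (int j = 0; j < ny; j++) line[j] = out[base + (R_xlen_t)nx * j];
          conv1d(line, res, ker, ny);
          for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = res[j];
        }
    } else {
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          R_xlen_t base = i + (R_xlen_t)nx * j;
          for (int k = 0; k < nz; k++) line[k] = out[base + stride * k];
          conv1d(line, res, ker, nz);
          for (int k = 0; k < nz; k++) out[base + stride * k] = res[k];
        }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface extraction: marching tetrahedra on the Kuhn (6-tet) cube split.
// The split is translation-invariant, so shared cube faces carry the same
// diagonal and the mesh is watertight when the field is below `level` on the
// whole array boundary. Vertices are deduplicated per lattice edge.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_march_tetra(NumericVector field, IntegerVector dim, NumericVector spacing,
                     NumericVector origin, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  // Kuhn tetrahedra: corner id = x + 2y + 4z
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  static const int cx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  static const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto interp = [&](R_xlen_t ga, R_xlen_t gb, double fa, double fb) -> int {
    uint64_t key = ga < gb ? ((uint64_t)ga << 32) | (uint64_t)gb
                           : ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int ia = ga % nx, ja = (ga / nx) % ny, ka = ga / sz;
    int ib = gb % nx, jb = (gb / nx) % ny, kb = gb / sz;
    vx.push_back(origin[0] + spacing[0] * (ia + t * (ib - ia)));
    vy.push_back(origin[1] + spacing[1] * (ja + t * (jb - ja)));
    vz.push_back(origin[2] + spacing[2] * (ka + t * (kb - ka)));
    int id = (int)vx.size() - 1;
    edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, int inside_corner_vid) {
    // orient so the normal points from inside to outside using the inside corner
    // inside_corner_vid: -1 flag handled by caller via sign convention
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
    (void)inside_corner_vid;
  };

  double f[8];
  R_xlen_t g[8];
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          g[c] = (i + cx[c]) + sy * (R_xlen_t)(j + cy[c]) + sz * (R_xlen_t)(k + cz[c]);
          f[c] = field[g[c]];
          if (f[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          const int* T = tets[t];
          int in[4], nin = 0, nout = 0, outv[4];
          for (int c = 0; c < 4; c++) {
            if (f[T[c]] > level) in[nin++] = T[c]; else outv[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int a = interp(g[in[0]], g[outv[0]], f[in[0]], f[outv[0]]);
            int b = interp(g[in[0]], g[outv[1]], f[in[0]], f[outv[1]]);
            int c2 = interp(g[in[0]], g[outv[2]], f[in[0]], f[outv[2]]);
            // orient outward: normal away from inside corner
            double px = origin[0] + spacing[0] * (i + cx[in[0]]);
            double py = origin[1] + spacing[1] * (j + cy[in[0]]);
            double pz = origin[2] + spacing[2] * (k + cz[in[0]]);
            double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
            double wx = vx[c2] - vx[a], wy = vy[c2] - vy[a], wz = vz[c2] - vz[a];
            double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
            double dot = nxv * (vx[a] - px) + nyv * (vy[a] - py) + nzv * (vz[a] - pz);
            if (dot >= 0) emit(a, b, c2, -1); else emit(a, c2, b, -1);
          } else if (nin == 3) {
            int a = interp(g[outv[0]], g[in[0]], f[outv[0]], f[in[0]]);
            int b = interp(g[outv[0]], g[in[1]], f[outv[0]], f[in[1]]);
            int c2 = interp(g[outv[0]], g[in[2]], f[outv[0]], f[in[2]]);
            double px = origin[0] + spacing[0] * (i + cx[outv[0]]);
            double py = origin[1] + spacing[1] * (j + cy[outv[0]]);
            double pz = origin[2] + spacing[2] * (k + cz[outv[0]]);
            double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
            double wx = vx[c2] - vx[a], wy = vy[c2] - vy[a], wz = vz[c2] - vz[a];
            double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
            // outward = toward the single outside corner
            double dot = nxv * (px - vx[a]) + nyv * (py - vy[a]) + nzv * (pz - vz[a]);
            if (dot >= 0) emit(a, b, c2, -1); else emit(a, c2, b, -1);
          } else { // 2 in, 2 out -> quad
            int a = interp(g[in[0]], g[outv[0]], f[in[0]], f[outv[0]]);
            int b = interp(g[in[0]], g[outv[1]], f[in[0]], f[outv[1]]);
            int c2 = interp(g[in[1]], g[outv[1]], f[in[1]], f[outv[1]]);
            int d = interp(g[in[1]], g[outv[0]], f[in[1]], f[outv[0]]);
            double px = origin[0] + spacing[0] * (i + cx[in[0]]);
            double py = origin[1] + spacing[1] * (j + cy[in[0]]);
            double pz = origin[2] + spacing[2] * (k + cz[in[0]]);
            double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
            double wx = vx[c2] - vx[a], wy = vy[c2] - vy[a], wz = vz[c2] - vz[a];
            double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
            double dot = nxv * (vx[a] - px) + nyv * (vy[a] - py) + nzv * (vz[a] - pz);
            if (dot >= 0) { emit(a, b, c2, -1); emit(a, c2, d, -1); }
            else { emit(a, c2, b, -1); emit(a, d, c2, -1); }
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int p = 0; p < nv; p++) { V(p, 0) = vx[p]; V(p, 1) = vy[p]; V(p, 2) = vz[p]; }
  IntegerMatrix Tm(nt, 3);
  for (int p = 0; p < nt; p++) {
    Tm(p, 0) = tri[3 * p] + 1; Tm(p, 1) = tri[3 * p + 1] + 1; Tm(p, 2) = tri[3 * p + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}

// ---------------------------------------------------------------------------
// Simple-point test: deleting the voxel preserves 26-connectivity of the
// foreground and 6-connectivity of the background (Bertrand & Malandain).
// ---------------------------------------------------------------------------
static inline int nb_index(int dx, int dy, int dz) { return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1); }

static bool is_simple(const int* nb) {
  // nb: 27 flags (centre at 13), foreground = 1. Centre value ignored.
  // C*: one 26-component of foreground in N26
  int seen[27] = {0};
  int nfg = 0, first = -1;
  for (int p = 0; p < 27; p++)
    if (p != 13 && nb[p]) { nfg++; if (first < 0) first = p; }
  if (nfg == 0) return false; // isolated: deletion removes a component
  // BFS over 26-adjacency
  int stack[27], sp = 0;
  stack[sp++] = first; seen[first] = 1;
  int cnt = 1;
  while (sp) {
    int p = stack[--sp];
    int px = p % 3, py = (p / 3) % 3, pz = p / 9;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int qx = px + dx, qy = py + dy, qz = pz + dz;
          if (qx < 0 || qx > 2 || qy < 0 || qy > 2 || qz < 0 || qz > 2) continue;
          int q = qx + 3 * qy + 9 * qz;
          if (q == 13 || seen[q] || !nb[q]) continue;
          seen[q] = 1; stack[sp++] = q; cnt++;
        }
  }
  if (cnt != nfg) return false;
  // Background: 6-components within N18 that are 6-adjacent to the centre; must be exactly 1
  static const int n18[18] = { // offsets with |dx|+|dy|+|dz| <= 2, not centre, not corners
    nb_index(-1,0,0), nb_index(1,0,0), nb_index(0,-1,0), nb_index(0,1,0),
    nb_index(0,0,-1), nb_index(0,0,1),
    nb_index(-1,-1,0), nb_index(-1,1,0), nb_index(1,-1,0), nb_index(1,1,0),
    nb_index(-1,0,-1), nb_index(-1,0,1), nb_index(1,0,-1), nb_index(1,0,1),
    nb_index(0,-1,-1), nb_index(0,-1,1), nb_index(0,1,-1), nb_index(0,1,1)};
  bool in18[27] = {false};
  for (int t = 0; t < 18; t++) in18[n18[t]] = true;
  static const int face6[6] = {
    nb_index(-1,0,0), nb_index(1,0,0), nb_index(0,-1,0),
    nb_index(0,1,0), nb_index(0,0,-1), nb_index(0,0,1)};
  int seenb[27] = {0};
  int ncomp = 0;
  for (int t0 = 0; t0 < 6; t0++) {
    int s = face6[t0];
    if (nb[s] || seenb[s]) continue; // must be background, unvisited
    ncomp++;
    if (ncomp > 1) return false;
    int stack2[27], sp2 = 0;
    stack2[sp2++] = s; seenb[s] = 1;
    while (sp2) {
      int p = stack2[--sp2];
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      static const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int t = 0; t < 6; t++) {
        int qx = px + d6[t][0], qy = py + d6[t][1], qz = pz + d6[t][2];
        if (qx < 0 || qx > 2 || qy < 0 || qy > 2 || qz < 0 || qz > 2) continue;
        int q = qx + 3 * qy + 9 * qz;
        if (q == 13 || !in18[q] || nb[q] || seenb[q]) continue;
        seenb[q] = 1; stack2[sp2++] = q;
      }
    }
  }
  return ncomp == 1;
}

// ---------------------------------------------------------------------------
// Distance-ordered homotopic thinning to a curve skeleton. Border voxels are
// removed in increasing distance-transform order when simple and not chain
// endpoints (< 2 foreground 26-neighbours).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim, NumericVector dtsq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> fg(n);
  for (R_xlen_t i = 0; i < n; i++) fg[i] = mask[i] ? 1 : 0;

  auto at = [&](int x, int y, int z) -> uint8_t {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return fg[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto count26 = [&](int x, int y, int z) {
    int c = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          c += at(x + dx, y + dy, z + dz);
        }
    return c;
  };
  auto border6 = [&](int x, int y, int z) {
    return !at(x - 1, y, z) || !at(x + 1, y, z) || !at(x, y - 1, z) ||
           !at(x, y + 1, z) || !at(x, y, z - 1) || !at(x, y, z + 1);
  };

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  std::vector<uint8_t> queued(n, 0);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (fg[idx] && border6(x, y, z)) { pq.push({dtsq[idx], idx}); queued[idx] = 1; }
      }

  int nb[27];
  while (!pq.empty()) {
    R_xlen_t idx = pq.top().second;
    pq.pop();
    queued[idx] = 0;
    if (!fg[idx]) continue;
    int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
    if (!border6(x, y, z)) continue;
    if (count26(x, y, z) < 2) continue; // endpoint: keep
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++)
          nb[nb_index(dx, dy, dz)] = at(x + dx, y + dy, z + dz);
    if (!is_simple(nb)) continue;
    fg[idx] = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int qx2 = x + dx, qy2 = y + dy, qz2 = z + dz;
          if (qx2 < 0 || qx2 >= nx || qy2 < 0 || qy2 >= ny || qz2 < 0 || qz2 >= nz) continue;
          R_xlen_t q = qx2 + (R_xlen_t)nx * (qy2 + (R_xlen_t)ny * qz2);
          if (fg[q] && !queued[q]) { pq.push({dtsq[q], q}); queued[q] = 1; }
        }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Single-source Dijkstra over foreground voxels (26-neighbourhood) with the
// medial edge cost length / (clearance + eps)^2, clearance = mean endpoint DT.
// Returns predecessor array (1-based, 0 = unreached/source marker handled in R).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_dijkstra(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                  NumericVector dt_mm, int source0, IntegerVector targets0, double eps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> dist(n, INF);
  std::vector<R_xlen_t> pred(n, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[source0] = 0.0;
  pq.push({0.0, source0});
  int remaining = targets0.size();
  std::vector<uint8_t> is_target(n, 0);
  for (int t = 0; t < targets0.size(); t++) is_target[targets0[t]] = 1;

  int offs[26][3], noff = 0;
  double elen[26];
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        offs[noff][0] = dx; offs[noff][1] = dy; offs[noff][2] = dz;
        elen[noff] = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                               dy * dy * spacing[1] * spacing[1] +
                               dz * dz * spacing[2] * spacing[2]);
        noff++;
      }

  while (!pq.empty()) {
    double du = pq.top().first;
    R_xlen_t u = pq.top().second;
    pq.pop();
    if (du > dist[u]) continue;
    if (is_target[u]) { is_target[u] = 0; if (--remaining == 0) break; }
    int x = u % nx, y = (u / nx) % ny, z = u / ((R_xlen_t)nx * ny);
    for (int t = 0; t < 26; t++) {
      int vx2 = x + offs[t][0], vy2 = y + offs[t][1], vz2 = z + offs[t][2];
      if (vx2 < 0 || vx2 >= nx || vy2 < 0 || vy2 >= ny || vz2 < 0 || vz2 >= nz) continue;
      R_xlen_t v = vx2 + (R_xlen_t)nx * (vy2 + (R_xlen_t)ny * vz2);
      if (!mask[v]) continue;
      double clear = 0.5 * (dt_mm[u] + dt_mm[v]) + eps;
      double w = elen[t] / (clear * clear);
      if (dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        pred[v] = u;
        pq.push({dist[v], v});
      }
    }
  }
  NumericVector distout(targets0.size());
  List paths(targets0.size());
  for (int t = 0; t < targets0.size(); t++) {
    R_xlen_t tgt = targets0[t];
    distout[t] = dist[tgt];
    std::vector<int> path;
    if (std::isfinite(dist[tgt])) {
      R_xlen_t cur = tgt;
      while (cur != -1) { path.push_back((int)cur + 1); cur = pred[cur]; }
      std::reverse(path.begin(), path.end());
    }
    paths[t] = IntegerVector(path.begin(), path.end());
  }
  return List::create(_["paths"] = paths, _["cost"] = distout);
}

// ---------------------------------------------------------------------------
// Per-axial-slice count of 8-connected foreground components (union-find).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_slice_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector counts(nz);
  std::vector<int> lab(nx * ny);
  std::vector<int> parent;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int k = 0; k < nz; k++) {
    std::fill(lab.begin(), lab.end(), -1);
    parent.clear();
    R_xlen_t base = (R_xlen_t)nx * ny * k;
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (!mask[base + i + (R_xlen_t)nx * j]) continue;
        int best = -1;
        // neighbours already scanned: W, NW, N, NE
        static const int doff[4][2] = {{-1, 0}, {-1, -1}, {0, -1}, {1, -1}};
        int labs[4], nl = 0;
        for (int t = 0; t < 4; t++) {
          int qi = i + doff[t][0], qj = j + doff[t][1];
          if (qi < 0 || qi >= nx || qj < 0) continue;
          int l = lab[qi + nx * qj];
          if (l >= 0) labs[nl++] = find(l);
        }
        if (nl == 0) {
          best = (int)parent.size();
          parent.push_back(best);
        } else {
          best = labs[0];
          for (int t = 1; t < nl; t++) {
            int r = labs[t];
            if (r != best) parent[r] = best;
          }
        }
        lab[i + nx * j] = best;
      }
    int c = 0;
    for (size_t a = 0; a < parent.size(); a++)
      if (parent[a] == (int)a) c++;
    counts[k] = c;
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Largest 26-connected foreground component.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> comp(n, -1);
  int ncomp = 0;
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || comp[s] >= 0) continue;
    R_xlen_t size = 0;
    stack.push_back(s);
    comp[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t u = stack.back();
      stack.pop_back();
      size++;
      int x = u % nx, y = (u / nx) % ny, z = u / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int qx = x + dx, qy = y + dy, qz = z + dz;
            if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz) continue;
            R_xlen_t q = qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
            if (mask[q] && comp[q] < 0) { comp[q] = ncomp; stack.push_back(q); }
          }
    }
    sizes.push_back(size);
    ncomp++;
  }
  int best = 0;
  for (int c = 1; c < ncomp; c++)
    if (sizes[c] > sizes[best]) best = c;
  LogicalVector out(n);
  if (ncomp > 0)
    for (R_xlen_t i = 0; i < n; i++) out[i] = comp[i] == best;
  return out;
}

// ---------------------------------------------------------------------------
// Voxelize a set of tubes (polyline centre curves with per-sample lumen radius
// and thrombus thickness). Each voxel is assigned to its nearest curve sample;
// lumen if within the lumen radius there, thrombus if within radius+thickness.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_voxelize_tubes(IntegerVector dim, NumericVector spacing, NumericVector origin,
                        List curves) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<float> d2min(n, std::numeric_limits<float>::infinity());
  std::vector<float> rl(n, 0.0f), ro(n, 0.0f);
  const double sx = spacing[0], sy2 = spacing[1], sz2 = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  for (int c = 0; c < curves.size(); c++) {
    List cur = curves[c];
    NumericMatrix P = cur["points"];
    NumericVector R = cur["radius"];
    NumericVector Th = cur["thickness"];
    for (int s = 0; s < P.nrow(); s++) {
      double px = P(s, 0), py = P(s, 1), pz = P(s, 2);
      double rad = R[s] + Th[s];
      double box = rad + std::max(sx, std::max(sy2, sz2));
      int i0 = std::max(0, (int)std::ceil((px - box - ox) / sx));
      int i1 = std::min(nx - 1, (int)std::floor((px + box - ox) / sx));
      int j0 = std::max(0, (int)std::ceil((py - box - oy) / sy2));
      int j1 = std::min(ny - 1, (int)std::floor((py + box - oy) / sy2));
      int k0 = std::max(0, (int)std::ceil((pz - box - oz) / sz2));
      int k1 = std::min(nz - 1, (int)std::floor((pz + box - oz) / sz2));
      for (int k = k0; k <= k1; k++) {
        double dz = oz + sz2 * k - pz;
        for (int j = j0; j <= j1; j++) {
          double dy = oy + sy2 * j - py;
          double dyz = dy * dy + dz * dz;
          R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int i = i0; i <= i1; i++) {
            double dx = ox + sx * i - px;
            float d2 = (float)(dx * dx + dyz);
            R_xlen_t idx = base + i;
            if (d2 < d2min[idx]) {
              d2min[idx] = d2;
              rl[idx] = (float)R[s];
              ro[idx] = (float)(R[s] + Th[s]);
            }
          }
        }
      }
    }
  }
  // The stamped boxes are bounded by each sample's own radius, so a voxel
  // outside its true nearest (thin) sample's box can be claimed by a farther,
  // fatter sample (sphere-union creep, which only adds foreground). Verify
  // every candidate foreground voxel against the exact nearest sample found
  // by a z-windowed search over all samples.
  int ntot = 0;
  for (int c = 0; c < curves.size(); c++) {
    List cur = curves[c];
    NumericMatrix P = cur["points"];
    ntot += P.nrow();
  }
  std::vector<double> sx_(ntot), sy_(ntot), sz_(ntot), sr_(ntot), st_(ntot);
  {
    int p = 0;
    for (int c = 0; c < curves.size(); c++) {
      List cur = curves[c];
      NumericMatrix P = cur["points"];
      NumericVector R = cur["radius"];
      NumericVector Th = cur["thickness"];
      for (int s = 0; s < P.nrow(); s++, p++) {
        sx_[p] = P(s, 0); sy_[p] = P(s, 1); sz_[p] = P(s, 2);
        sr_[p] = R[s]; st_[p] = Th[s];
      }
    }
    std::vector<int> ord(ntot);
    for (int i = 0; i < ntot; i++) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return sz_[a] < sz_[b]; });
    std::vector<double> tx(ntot), ty(ntot), tz(ntot), tr(ntot), tt(ntot);
    for (int i = 0; i < ntot; i++) {
      tx[i] = sx_[ord[i]]; ty[i] = sy_[ord[i]]; tz[i] = sz_[ord[i]];
      tr[i] = sr_[ord[i]]; tt[i] = st_[ord[i]];
    }
    sx_.swap(tx); sy_.swap(ty); sz_.swap(tz); sr_.swap(tr); st_.swap(tt);
  }

  IntegerVector lumen(n), thrombus(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (!std::isfinite((double)d2min[i])) continue;
    double d = std::sqrt((double)d2min[i]);
    if (d > ro[i]) continue; // background candidate stays background
    // exact nearest sample within |z - vz| <= d (+ slack)
    double vx2 = ox + sx * (double)(i % nx);
    double vy2 = oy + sy2 * (double)((i / nx) % ny);
    double vz2 = oz + sz2 * (double)(i / ((R_xlen_t)nx * ny));
    double win = d + 1e-6;
    int lo = (int)(std::lower_bound(sz_.begin(), sz_.end(), vz2 - win) - sz_.begin());
    int hi = (int)(std::upper_bound(sz_.begin(), sz_.end(), vz2 + win) - sz_.begin());
    double best = INF;
    double brl = 0, bro = 0;
    for (int s = lo; s < hi; s++) {
      double ddx = sx_[s] - vx2, ddy = sy_[s] - vy2, ddz = sz_[s] - vz2;
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best) { best = d2; brl = sr_[s]; bro = sr_[s] + st_[s]; }
    }
    if (!std::isfinite(best)) continue;
    double dn = std::sqrt(best);
    if (dn <= brl) lumen[i] = 1;
    else if (dn <= bro) thrombus[i] = 1;
  }
  return List::create(_["lumen"] = lumen, _["thrombus"] = thrombus);
}
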
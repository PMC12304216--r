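// Low-level 3D grid routines shared by the geometry pipeline.
// Conventions: volumes are R arrays dim (nx, ny, nz), column-major,
// linear index = i + nx*(j + ny*k) with 0-based i,j,k here.
// World coordinates (mm) = 0-based voxel index * spacing.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared-distance lower envelope of
// parabolas, applied separably along each axis with its own sample spacing).
// Input: f = 0 at background voxels, +inf at foreground. Output: squared mm.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s;
    double sden, snum;
    while (true) {
      double vv = (double)v[k] * s;
      snum = (f[q] + qq * qq) - (f[v[k]] + vv * vv);
      sden = 2.0 * qq - 2.0 * vv;
      double sint = snum / sden;
      if (sint <= z[k]) { --k; } else {
        ++k; v[k] = q; z[k] = sint; z[k + 1] = INF; break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * s;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  // large finite sentinel keeps the parabola arithmetic well-defined
  double ex0 = nx * spacing[0], ex1 = ny * spacing[1], ex2 = nz * spacing[2];
  const double BIG = 4.0 * (ex0 * ex0 + ex1 * ex1 + ex2 * ex2) + 1.0;
  std::vector<double> g(n);
  for (int t = 0; t < n; ++t) g[t] = mask[t] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }

  NumericVector out(n);
  for (int t = 0; t < n; ++t) out[t] = mask[t] ? std::sqrt(g[t]) : 0.0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test (foreground 26-connectivity, background 6-connectivity).
// A voxel is simple iff (a) its 26-neighbourhood foreground forms exactly one
// 26-connected component, and (b) the background voxels among its 18
// face/edge neighbours form exactly one 6-connected component that is
// 6-adjacent to the voxel.
static bool is_simple(const std::vector<unsigned char>& m,
                      int i, int j, int k, int nx, int ny, int nz) {
  unsigned char nb[27]; // 3x3x3 block, index a + 3*(b + 3*c), a,b,c in 0..2
  for (int c = 0; c < 3; ++c)
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        int ii = i + a - 1, jj = j + b - 1, kk = k + c - 1;
        unsigned char val = 0;
        if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
          val = m[idx3(ii, jj, kk, nx, ny)];
        nb[a + 3 * (b + 3 * c)] = val;
      }
  nb[13] = 0; // centre removed

  // (a) 26-components of foreground among the 26 neighbours
  int compA = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++compA;
    if (compA > 1) return false;
    int top = 0; stack[top++] = s; seen[s] = true;
    while (top > 0) {
      int u = stack[--top];
      int ua = u % 3, ub = (u / 3) % 3, uc = u / 9;
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            if (!da && !db && !dc) continue;
            int va = ua + da, vb = ub + db, vc = uc + dc;
            if (va < 0 || va > 2 || vb < 0 || vb > 2 || vc < 0 || vc > 2) continue;
            int vv = va + 3 * (vb + 3 * vc);
            if (vv == 13 || seen[vv] || !nb[vv]) continue;
            seen[vv] = true; stack[top++] = vv;
          }
    }
  }
  if (compA != 1) return false;

  // (b) 6-components of background among the 18 face/edge neighbours,
  //     counting only components containing a face neighbour.
  bool in18[27];
  for (int s = 0; s < 27; ++s) {
    int a = s % 3 - 1, b = (s / 3) % 3 - 1, c = s / 9 - 1;
    int nz_ = (a != 0) + (b != 0) + (c != 0);
    in18[s] = (nz_ == 1 || nz_ == 2);
  }
  int compB = 0;
  bool seenB[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seenB[s]) continue;
    int a = s % 3 - 1, b = (s / 3) % 3 - 1, c = s / 9 - 1;
    bool isFace = (std::abs(a) + std::abs(b) + std::abs(c)) == 1;
    if (!isFace) continue; // grow components from face neighbours only
    ++compB;
    if (compB > 1) return false;
    int top = 0; stack[top++] = s; seenB[s] = true;
    while (top > 0) {
      int u = stack[--top];
      int ua = u % 3, ub = (u / 3) % 3, uc = u / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int va = ua + d6[t][0], vb = ub + d6[t][1], vc = uc + d6[t][2];
        if (va < 0 || va > 2 || vb < 0 || vb > 2 || vc < 0 || vc > 2) continue;
        int vv = va + 3 * (vb + 3 * vc);
        if (vv == 13 || !in18[vv] || seenB[vv] || nb[vv]) continue;
        seenB[vv] = true; stack[top++] = vv;
      }
    }
  }
  return compB == 1;
}

static int count_fg_neighbours26(const std::vector<unsigned char>& m,
                                 int i, int j, int k, int nx, int ny, int nz) {
  int cnt = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        if (!da && !db && !dc) continue;
        int ii = i + da, jj = j + db, kk = k + dc;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        if (m[idx3(ii, jj, kk, nx, ny)]) ++cnt;
      }
  return cnt;
}

// Distance-ordered homotopic thinning to a one-voxel-wide curve skeleton.
// Voxels are deleted in increasing distance-field order when deletion
// preserves topology (simple point) and the voxel is neither a curve
// endpoint nor an anchor. Anchors are geodesic extremities on the medial
// locus: per component, local maxima of (geodesic distance from the
// EDT-maximal source + 2 * EDT). Without them homotopic thinning of a
// contractible tube retracts its ends without bound.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims,
                         NumericVector edt, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<unsigned char> m(n);
  for (int t = 0; t < n; ++t) m[t] = mask[t] ? 1 : 0;

  // --- component labelling (26-connected)
  std::vector<int> comp(n, 0);
  int ncomp = 0;
  {
    std::vector<int> stack;
    for (int s = 0; s < n; ++s) {
      if (!m[s] || comp[s]) continue;
      ++ncomp;
      comp[s] = ncomp; stack.push_back(s);
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
        for (int dc = -1; dc <= 1; ++dc)
          for (int db = -1; db <= 1; ++db)
            for (int da = -1; da <= 1; ++da) {
              if (!da && !db && !dc) continue;
              int ii = i + da, jj = j + db, kk = k + dc;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              int v = idx3(ii, jj, kk, nx, ny);
              if (m[v] && !comp[v]) { comp[v] = ncomp; stack.push_back(v); }
            }
      }
    }
  }

  // --- per-component EDT-maximal source voxels
  std::vector<int> source(ncomp + 1, -1);
  for (int t = 0; t < n; ++t) {
    if (!m[t]) continue;
    int c = comp[t];
    if (source[c] < 0 || edt[t] > edt[source[c]]) source[c] = t;
  }

  // --- geodesic distance (mm) inside the mask from the sources
  std::vector<double> gd(n, std::numeric_limits<double>::infinity());
  {
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    for (int c = 1; c <= ncomp; ++c) {
      gd[source[c]] = 0.0;
      pq.push(QE(0.0, source[c]));
    }
    while (!pq.empty()) {
      double du = pq.top().first; int u = pq.top().second; pq.pop();
      if (du > gd[u]) continue;
      int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            if (!da && !db && !dc) continue;
            int ii = i + da, jj = j + db, kk = k + dc;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            int v = idx3(ii, jj, kk, nx, ny);
            if (!m[v]) continue;
            double ex = da * spacing[0], ey = db * spacing[1],
                   ez = dc * spacing[2];
            double alt = du + std::sqrt(ex * ex + ey * ey + ez * ez);
            if (alt < gd[v]) { gd[v] = alt; pq.push(QE(alt, v)); }
          }
    }
  }

  // --- anchors: local maxima of gd + 2*edt over the 26-neighbourhood,
  // restricted to medial voxels (EDT within 60% of the component maximum);
  // without the restriction the rim of a flat-ended tube anchors spurs.
  std::vector<double> cmax(ncomp + 1, 0.0);
  for (int t = 0; t < n; ++t)
    if (m[t] && edt[t] > cmax[comp[t]]) cmax[comp[t]] = edt[t];
  std::vector<unsigned char> anchor(n, 0);
  // the geodesic source (gd = 0) and the geodesic-farthest voxel are the two
  // extremities of each component: anchor both explicitly so neither end can
  // retract even when the local-maximum test misses it (e.g. clipped,
  // tapering fragments next to a junction)
  for (int c = 1; c <= ncomp; ++c) anchor[source[c]] = 1;
  {
    // Both extremities of each component, by the same gd + 2*edt score as
    // the local-maximum anchors (the medial-depth weight keeps them on the
    // axis rather than on cap rims or thin territory wedges): first the
    // score-maximal voxel e1, then, from a second geodesic sweep seeded at
    // e1, the score-maximal voxel again -- the opposite tip.
    std::vector<int> e1(ncomp + 1, -1);
    for (int t = 0; t < n; ++t) {
      if (!m[t]) continue;
      int c = comp[t];
      double sc = gd[t] + 2.0 * edt[t];
      if (e1[c] < 0 || sc > gd[e1[c]] + 2.0 * edt[e1[c]]) e1[c] = t;
    }
    std::vector<double> gd2(n, std::numeric_limits<double>::infinity());
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq2;
    for (int c = 1; c <= ncomp; ++c)
      if (e1[c] >= 0) { gd2[e1[c]] = 0.0; pq2.push(QE(0.0, e1[c])); }
    while (!pq2.empty()) {
      double du = pq2.top().first; int u = pq2.top().second; pq2.pop();
      if (du > gd2[u]) continue;
      int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            if (!da && !db && !dc) continue;
            int ii = i + da, jj = j + db, kk = k + dc;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            int v = idx3(ii, jj, kk, nx, ny);
            if (!m[v]) continue;
            double ex = da * spacing[0], ey = db * spacing[1],
                   ez = dc * spacing[2];
            double alt = du + std::sqrt(ex * ex + ey * ey + ez * ez);
            if (alt < gd2[v]) { gd2[v] = alt; pq2.push(QE(alt, v)); }
          }
    }
    std::vector<int> e2(ncomp + 1, -1);
    for (int t = 0; t < n; ++t) {
      if (!m[t]) continue;
      int c = comp[t];
      double sc = gd2[t] + 2.0 * edt[t];
      if (e2[c] < 0 || sc > gd2[e2[c]] + 2.0 * edt[e2[c]]) e2[c] = t;
    }
    for (int c = 1; c <= ncomp; ++c) {
      if (e1[c] >= 0) anchor[e1[c]] = 1;
      if (e2[c] >= 0) anchor[e2[c]] = 1;
    }
  }
  for (int t = 0; t < n; ++t) {
    if (!m[t]) continue;
    if (edt[t] < 0.6 * cmax[comp[t]]) continue;
    double sc = gd[t] + 2.0 * edt[t];
    int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
    bool ismax = true;
    for (int dc = -1; dc <= 1 && ismax; ++dc)
      for (int db = -1; db <= 1 && ismax; ++db)
        for (int da = -1; da <= 1 && ismax; ++da) {
          if (!da && !db && !dc) continue;
          int ii = i + da, jj = j + db, kk = k + dc;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          int v = idx3(ii, jj, kk, nx, ny);
          if (m[v] && gd[v] + 2.0 * edt[v] > sc + 1e-9) ismax = false;
        }
    if (ismax) anchor[t] = 1;
  }

  typedef std::pair<double, int> QE; // (priority, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int t = 0; t < n; ++t) if (m[t]) pq.push(QE(edt[t], t));

  while (!pq.empty()) {
    int t = pq.top().second; pq.pop();
    if (!m[t]) continue;
    if (anchor[t]) continue;
    int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
    // no blanket endpoint protection: unanchored strand ends retract until
    // they reach an anchor, so ends land on the medial extremities
    if (!is_simple(m, i, j, k, nx, ny, nz)) continue;
    m[t] = 0;
    for (int dc = -1; dc <= 1; ++dc)
      for (int db = -1; db <= 1; ++db)
        for (int da = -1; da <= 1; ++da) {
          if (!da && !db && !dc) continue;
          int ii = i + da, jj = j + db, kk = k + dc;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          int u = idx3(ii, jj, kk, nx, ny);
          if (m[u]) pq.push(QE(edt[u], u));
        }
  }

  LogicalVector out(n);
  for (int t = 0; t < n; ++t) out[t] = m[t] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Dijkstra minimal-cost path on the 26-connected voxel grid.
// Edge cost u->v = |step in mm| / (field[v] + eps): paths prefer
// lumen-central (high distance-field) voxels. Deterministic: the queue
// breaks cost ties by linear voxel index, neighbours are relaxed in a fixed
// order and only strict improvements update the predecessor.
// [[Rcpp::export]]
List cpp_trace_path(NumericVector field, IntegerVector dims,
                    NumericVector spacing, int start, int end,
                    double eps, double max_cost) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> prev(n, -1);

  int offs[26][3]; double olen[26]; int no = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        if (!da && !db && !dc) continue;
        offs[no][0] = da; offs[no][1] = db; offs[no][2] = dc;
        double ex = da * spacing[0], ey = db * spacing[1], ez = dc * spacing[2];
        olen[no] = std::sqrt(ex * ex + ey * ey + ez * ez);
        ++no;
      }

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[start] = 0.0;
  pq.push(QE(0.0, start));
  while (!pq.empty()) {
    double du = pq.top().first; int u = pq.top().second; pq.pop();
    if (du > dist[u]) continue;
    if (u == end) break;
    if (du > max_cost) break;
    int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
    for (int t = 0; t < 26; ++t) {
      int ii = i + offs[t][0], jj = j + offs[t][1], kk = k + offs[t][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int v = idx3(ii, jj, kk, nx, ny);
      double w = olen[t] / (field[v] + eps);
      double alt = du + w;
      if (alt < dist[v]) {
        dist[v] = alt; prev[v] = u;
        pq.push(QE(alt, v));
      }
    }
  }

  bool ok = std::isfinite(dist[end]) && dist[end] <= max_cost;
  IntegerVector path;
  if (ok) {
    std::vector<int> rev;
    for (int u = end; u != -1; u = prev[u]) rev.push_back(u);
    path = IntegerVector(rev.size());
    for (size_t t = 0; t < rev.size(); ++t) path[t] = rev[rev.size() - 1 - t];
  }
  return List::create(_["reachable"] = ok,
                      _["cost"] = ok ? dist[end] : NA_REAL,
                      _["path"] = path); // 0-based linear indices
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at continuous 0-based voxel coordinates.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dims,
                   NumericMatrix pts, double pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  LogicalVector inside(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = pad; inside[p] = false; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double v000 = vol[idx3(i0, j0, k0, nx, ny)], v100 = vol[idx3(i1, j0, k0, nx, ny)];
    double v010 = vol[idx3(i0, j1, k0, nx, ny)], v110 = vol[idx3(i1, j1, k0, nx, ny)];
    double v001 = vol[idx3(i0, j0, k1, nx, ny)], v101 = vol[idx3(i1, j0, k1, nx, ny)];
    double v011 = vol[idx3(i0, j1, k1, nx, ny)], v111 = vol[idx3(i1, j1, k1, nx, ny)];
    double c00 = v000 * (1 - fx) + v100 * fx;
    double c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx;
    double c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
    inside[p] = true;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// ---------------------------------------------------------------------------
// 26-connected component labelling of a binary grid.
// [[Rcpp::export]]
IntegerVector cpp_cc26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s); lab[s] = cur;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            if (!da && !db && !dc) continue;
            int ii = i + da, jj = j + db, kk = k + dc;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            int v = idx3(ii, jj, kk, nx, ny);
            if (mask[v] && !lab[v]) { lab[v] = cur; stack.push_back(v); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Binary dilation by `iter` passes of the 26-neighbourhood structuring element.
// [[Rcpp::export]]
LogicalVector cpp_dilate26(LogicalVector mask, IntegerVector dims, int iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<unsigned char> a(n), b(n);
  for (int t = 0; t < n; ++t) a[t] = mask[t] ? 1 : 0;
  for (int it = 0; it < iter; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int t = idx3(i, j, k, nx, ny);
          unsigned char v = a[t];
          if (!v) {
            for (int dc = -1; dc <= 1 && !v; ++dc)
              for (int db = -1; db <= 1 && !v; ++db)
                for (int da = -1; da <= 1 && !v; ++da) {
                  if (!da && !db && !dc) continue;
                  int ii = i + da, jj = j + db, kk = k + dc;
                  if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                  if (a[idx3(ii, jj, kk, nx, ny)]) v = 1;
                }
          }
          b[t] = v;
        }
    std::swap(a, b);
  }
  LogicalVector out(n);
  for (int t = 0; t < n; ++t) out[t] = a[t] != 0;
  out.attr("dim") = dims;
  return out;
}
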
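#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Shared voxel-grid helpers for the segmentation pipeline. All functions
// take a logical/numeric vector in R array order (column-major, dims d1,d2,d3)
// and 1-based linear indices on the R side.

static inline int lin(int i, int j, int k, const int *d) {
  return i + d[0] * (j + d[1] * k);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({{dx, dy, dz}});
      }
  int cur = 0;
  std::queue<int> q;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int v = lin(i, j, k, d);
        if (!mask[v] || lab[v]) continue;
        ++cur;
        lab[v] = cur;
        q.push(v);
        while (!q.empty()) {
          int w = q.front(); q.pop();
          int wi = w % d[0], wj = (w / d[0]) % d[1], wk = w / (d[0] * d[1]);
          for (size_t o = 0; o < offs.size(); ++o) {
            int ni = wi + offs[o][0], nj = wj + offs[o][1], nk = wk + offs[o][2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
              continue;
            int nv = lin(ni, nj, nk, d);
            if (mask[nv] && !lab[nv]) { lab[nv] = cur; q.push(nv); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform with feature (nearest-site) tracking.
// Felzenszwalb & Huttenlocher separable lower-envelope algorithm; the winning
// parabola is back-tracked per pass so each voxel also reports the linear
// index of its nearest feature voxel.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double> &f, const std::vector<int> &ff,
                 double step, std::vector<double> &out, std::vector<int> &of) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  out.assign(n, INF);
  of.assign(n, -1);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * step;
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s;
    for (;;) {
      double xv = v[k] * step;
      // abscissa where parabola q overtakes parabola v[k]; finite since f finite
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) { --k; continue; } // z[0] = -INF guards k >= 0
      break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) return; // no finite parabola in this line
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[kk + 1] < xq) ++kk;
    double dx = xq - v[kk] * step;
    out[q] = dx * dx + f[v[kk]];
    of[q] = ff[v[kk]];
  }
}

// [[Rcpp::export]]
List cpp_edt_feature(LogicalVector feature, IntegerVector dim,
                     NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<double> D(n);
  std::vector<int> F(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    D[v] = feature[v] ? 0.0 : INF;
    F[v] = feature[v] ? (int)v : -1;
  }
  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    int len = d[axis];
    double step = spacing[axis];
    std::vector<double> line(len), oline;
    std::vector<int> fline(len), ofl;
    int a1 = (axis == 0) ? 1 : 0;
    int a2 = (axis == 2) ? 1 : 2;
    for (int j = 0; j < d[a1]; ++j)
      for (int k = 0; k < d[a2]; ++k) {
        for (int i = 0; i < len; ++i) {
          int c[3]; c[axis] = i; c[a1] = j; c[a2] = k;
          int v = lin(c[0], c[1], c[2], d);
          line[i] = D[v]; fline[i] = F[v];
        }
        dt1d(line, fline, step, oline, ofl);
        for (int i = 0; i < len; ++i) {
          int c[3]; c[axis] = i; c[a1] = j; c[a2] = k;
          int v = lin(c[0], c[1], c[2], d);
          D[v] = oline[i]; F[v] = ofl[i];
        }
      }
  }
  NumericVector dist(n);
  IntegerVector idx(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    dist[v] = (D[v] == INF) ? R_PosInf : std::sqrt(D[v]);
    idx[v] = (F[v] < 0) ? NA_INTEGER : F[v] + 1; // 1-based for R
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential 3D thinning. A voxel is simple iff its
// 26-neighbourhood object set has exactly one 26-component and the background
// restricted to the 18-neighbourhood has exactly one 6-component touching a
// face neighbour (Bertrand-Malandain characterisation). Border voxels are
// deleted in increasing distance-transform order; curve endpoints are kept.
// ---------------------------------------------------------------------------

static const int NB27[27][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

static void neighborhood(const std::vector<char> &obj, const int *d,
                         int i, int j, int k, char nb[27]) {
  for (int t = 0; t < 27; ++t) {
    int ni = i + NB27[t][0], nj = j + NB27[t][1], nk = k + NB27[t][2];
    if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
      nb[t] = 0;
    else
      nb[t] = obj[lin(ni, nj, nk, d)];
  }
}

static int n26_count(const char nb[27]) {
  int c = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++c;
  return c;
}

static bool is_simple(const char nb[27]) {
  // object 26-components in N26*
  int compO = 0;
  bool seenO[27] = {false};
  for (int t = 0; t < 27; ++t) {
    if (t == 13 || !nb[t] || seenO[t]) continue;
    ++compO;
    std::queue<int> q; q.push(t); seenO[t] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || !nb[b] || seenO[b]) continue;
        int dx = std::abs(NB27[a][0] - NB27[b][0]);
        int dy = std::abs(NB27[a][1] - NB27[b][1]);
        int dz = std::abs(NB27[a][2] - NB27[b][2]);
        if (dx <= 1 && dy <= 1 && dz <= 1) { seenO[b] = true; q.push(b); }
      }
    }
  }
  if (compO != 1) return false;
  // background 6-components in N18 that touch a face neighbour
  int compB = 0;
  bool seenB[27] = {false};
  for (int t = 0; t < 27; ++t) {
    int man = std::abs(NB27[t][0]) + std::abs(NB27[t][1]) + std::abs(NB27[t][2]);
    if (man != 1 || nb[t] || seenB[t]) continue; // seed from face cells only
    ++compB;
    std::queue<int> q; q.push(t); seenB[t] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      for (int b = 0; b < 27; ++b) {
        int manb = std::abs(NB27[b][0]) + std::abs(NB27[b][1]) + std::abs(NB27[b][2]);
        if (manb < 1 || manb > 2 || nb[b] || seenB[b]) continue; // N18 background
        int dd = std::abs(NB27[a][0] - NB27[b][0]) + std::abs(NB27[a][1] - NB27[b][1]) +
                 std::abs(NB27[a][2] - NB27[b][2]);
        if (dd == 1) { seenB[b] = true; q.push(b); }
      }
    }
  }
  return compB == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim,
                       NumericVector priority) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<char> obj(n);
  for (R_xlen_t v = 0; v < n; ++v) obj[v] = mask[v] ? 1 : 0;
  char nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    // collect current border voxels
    std::vector<std::pair<double,int> > cand;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int v = lin(i, j, k, d);
          if (!obj[v]) continue;
          bool border = false;
          static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (int f = 0; f < 6 && !border; ++f) {
            int ni = i + F6[f][0], nj = j + F6[f][1], nk = k + F6[f][2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2] ||
                !obj[lin(ni, nj, nk, d)])
              border = true;
          }
          if (border) cand.push_back(std::make_pair(priority[v], v));
        }
    std::sort(cand.begin(), cand.end());
    for (size_t t = 0; t < cand.size(); ++t) {
      int v = cand[t].second;
      if (!obj[v]) continue;
      int i = v % d[0], j = (v / d[0]) % d[1], k = v / (d[0] * d[1]);
      neighborhood(obj, d, i, j, k, nb);
      if (n26_count(nb) <= 1) continue; // keep curve endpoints
      if (!is_simple(nb)) continue;
      obj[v] = 0;
      changed = true;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = obj[v] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// 26-neighbour adjacency edges between TRUE voxels (for skeleton graphs).
// Returns a 2-column matrix of 1-based linear indices, i < j.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_voxel_edges(LogicalVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  std::vector<int> from, to;
  // forward half of the 26-neighbourhood to avoid duplicates
  std::vector<std::array<int,3> > offs;
  for (int t = 14; t < 27; ++t) offs.push_back({{NB27[t][0], NB27[t][1], NB27[t][2]}});
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int v = lin(i, j, k, d);
        if (!mask[v]) continue;
        for (size_t o = 0; o < offs.size(); ++o) {
          int ni = i + offs[o][0], nj = j + offs[o][1], nk = k + offs[o][2];
          if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
            continue;
          int nv = lin(ni, nj, nk, d);
          if (mask[nv]) { from.push_back(v + 1); to.push_back(nv + 1); }
        }
      }
  IntegerMatrix out(from.size(), 2);
  for (size_t t = 0; t < from.size(); ++t) { out(t, 0) = from[t]; out(t, 1) = to[t]; }
  return out;
}

// ---------------------------------------------------------------------------
// Morphological box dilation by one voxel (26-neighbourhood).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_dilate1(LogicalVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector out(n, false);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        if (!mask[lin(i, j, k, d)]) continue;
        for (int t = 0; t < 27; ++t) {
          int ni = i + NB27[t][0], nj = j + NB27[t][1], nk = k + NB27[t][2];
          if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
            continue;
          out[lin(ni, nj, nk, d)] = true;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Paint Euclidean balls at given voxel centres (1-based linear indices).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_paint_balls(IntegerVector centers, NumericVector radii,
                              IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector out(n, false);
  for (R_xlen_t c = 0; c < centers.size(); ++c) {
    int v = centers[c] - 1;
    int ci = v % d[0], cj = (v / d[0]) % d[1], ck = v / (d[0] * d[1]);
    double r = radii[c];
    int ir = (int)std::floor(r);
    for (int dk = -ir; dk <= ir; ++dk)
      for (int dj = -ir; dj <= ir; ++dj)
        for (int di = -ir; di <= ir; ++di) {
          if (di * di + dj * dj + dk * dk > r * r) continue;
          int ni = ci + di, nj = cj + dj, nk = ck + dk;
          if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2])
            continue;
          out[lin(ni, nj, nk, d)] = true;
        }
  }
  return out;
}
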
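#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Uniform-grid spatial hash.  Key collisions only enlarge a candidate set
// (every candidate is re-checked by exact distance), so they are harmless.
static inline int64_t cell_key(int ix, int iy, int iz) {
  return static_cast<int64_t>(ix) * 73856093LL ^
         static_cast<int64_t>(iy) * 19349663LL ^
         static_cast<int64_t>(iz) * 83492791LL;
}

typedef std::unordered_map<int64_t, std::vector<int> > CellMap;

static CellMap build_grid3(const NumericMatrix &pts, double cell) {
  CellMap grid;
  for (int i = 0; i < pts.nrow(); ++i) {
    int ix = (int)std::floor(pts(i, 0) / cell);
    int iy = (int)std::floor(pts(i, 1) / cell);
    int iz = (int)std::floor(pts(i, 2) / cell);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }
  return grid;
}

struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_euclidean_cluster(NumericMatrix pts, double tol) {
  int n = pts.nrow();
  IntegerVector labels(n);
  if (n == 0) return labels;
  double tol2 = tol * tol;
  CellMap grid = build_grid3(pts, tol);
  DSU dsu(n);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(pts(i, 0) / tol);
    int iy = (int)std::floor(pts(i, 1) / tol);
    int iz = (int)std::floor(pts(i, 2) / tol);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellMap::const_iterator it =
              grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          const std::vector<int> &bucket = it->second;
          for (size_t b = 0; b < bucket.size(); ++b) {
            int j = bucket[b];
            if (j <= i) continue;
            double d0 = pts(i, 0) - pts(j, 0);
            double d1 = pts(i, 1) - pts(j, 1);
            double d2 = pts(i, 2) - pts(j, 2);
            if (d0 * d0 + d1 * d1 + d2 * d2 <= tol2) dsu.unite(i, j);
          }
        }
  }
  // relabel roots as consecutive 1-based component ids
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = dsu.find(i);
    std::unordered_map<int, int>::iterator it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; labels[i] = next; }
    else labels[i] = it->second;
  }
  return labels;
}

// 2D grid used by the alpha-shape edge test
static inline int64_t cell_key2(int ix, int iy) {
  return static_cast<int64_t>(ix) * 73856093LL ^
         static_cast<int64_t>(iy) * 19349663LL;
}

static CellMap build_grid2(const NumericVector &x, const NumericVector &y,
                           double cell) {
  CellMap grid;
  for (int i = 0; i < x.size(); ++i) {
    int ix = (int)std::floor(x[i] / cell);
    int iy = (int)std::floor(y[i] / cell);
    grid[cell_key2(ix, iy)].push_back(i);
  }
  return grid;
}

// true when no point other than i,j lies strictly inside the disk of
// radius alpha centred at (cx, cy)
static bool disk_empty(const NumericVector &x, const NumericVector &y,
                       const CellMap &grid, double cell, double alpha,
                       double cx, double cy, int i, int j) {
  double a2 = alpha * alpha * (1.0 - 1e-9);
  int ix = (int)std::floor(cx / cell);
  int iy = (int)std::floor(cy / cell);
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy) {
      CellMap::const_iterator it = grid.find(cell_key2(ix + dx, iy + dy));
      if (it == grid.end()) continue;
      const std::vector<int> &bucket = it->second;
      for (size_t b = 0; b < bucket.size(); ++b) {
        int k = bucket[b];
        if (k == i || k == j) continue;
        double ddx = x[k] - cx, ddy = y[k] - cy;
        if (ddx * ddx + ddy * ddy < a2) return false;
      }
    }
  return true;
}

//' Alpha-shape boundary edges of a planar point set.
//'
//' An (i, j) pair is a boundary edge when the two points are at most
//' 2*alpha apart and at least one of the two discs of radius alpha whose
//' boundary passes through both points contains no other point.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_alpha_edges(NumericVector x, NumericVector y, double alpha) {
  int n = x.size();
  std::vector<int> ei, ej;
  if (n >= 2) {
    double cell = alpha;
    CellMap grid = build_grid2(x, y, cell);
    double lim2 = 4.0 * alpha * alpha;
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor(x[i] / cell);
      int iy = (int)std::floor(y[i] / cell);
      for (int dx = -2; dx <= 2; ++dx)
        for (int dy = -2; dy <= 2; ++dy) {
          CellMap::const_iterator it = grid.find(cell_key2(ix + dx, iy + dy));
          if (it == grid.end()) continue;
          const std::vector<int> &bucket = it->second;
          for (size_t b = 0; b < bucket.size(); ++b) {
            int j = bucket[b];
            if (j <= i) continue;
            double ddx = x[j] - x[i], ddy = y[j] - y[i];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 > lim2 || d2 == 0.0) continue;
            double d = std::sqrt(d2);
            double h = std::sqrt(std::max(alpha * alpha - d2 / 4.0, 0.0));
            double mx = (x[i] + x[j]) / 2.0, my = (y[i] + y[j]) / 2.0;
            double ux = -ddy / d, uy = ddx / d;  // unit normal to the chord
            if (disk_empty(x, y, grid, cell, alpha, mx + h * ux, my + h * uy,
                           i, j) ||
                disk_empty(x, y, grid, cell, alpha, mx - h * ux, my - h * uy,
                           i, j)) {
              ei.push_back(i + 1);
              ej.push_back(j + 1);
            }
          }
        }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}
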
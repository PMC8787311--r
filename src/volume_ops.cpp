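// Low-level 3D volume primitives shared by the reconstruction and
// classification stages. Arrays arrive as flat vectors in R's column-major
// layout with dims = (ny, nx, nz); linear index = y + ny*(x + nx*z).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int lin(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<int> queue_;
  queue_.reserve(1024);
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue_.clear();
    queue_.push_back((int)start);
    size_t head = 0;
    while (head < queue_.size()) {
      int v = queue_[head++];
      int z = v / (ny * nx);
      int rem = v - z * ny * nx;
      int x = rem / ny;
      int y = rem - x * ny;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 &&
                (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
            int w = lin(yy, xx, zz, ny, nx);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              queue_.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on samples at
// positions i*s. f holds squared distances; INF where unseeded.
static void dt1d(const double *f, double *d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> zpos(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zpos[0] = -INF;
  zpos[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double xq = q * s;
    while (true) {
      int p = v[k];
      double xp = p * s;
      double sint = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * xq - 2 * xp);
      if (sint <= zpos[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        zpos[k] = sint;
        zpos[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zpos[k + 1] < xq) ++k;
    int p = v[k];
    double xp = p * s;
    double dd = xq - xp;
    d[q] = dd * dd + f[p];
  }
}

// Euclidean distance (um) from every voxel to the nearest TRUE voxel of
// `set`, with anisotropic spacing. Voxels inside the set get 0.
// [[Rcpp::export]]
NumericVector cpp_distance_to_set(LogicalVector set, IntegerVector dims,
                                  double dy, double dx, double dz) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (set.size() != n) stop("set length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  std::vector<double> g(n);
  bool any_seed = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    g[i] = set[i] ? 0.0 : INF;
    if (set[i]) any_seed = true;
  }
  if (!any_seed) {
    std::fill(out.begin(), out.end(), INF);
    return out;
  }
  std::vector<double> buf(std::max(ny, std::max(nx, nz)));
  std::vector<double> res(buf.size());
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      double *col = &g[lin(0, x, z, ny, nx)];
      dt1d(col, res.data(), ny, dy);
      std::copy(res.begin(), res.begin() + ny, col);
    }
  // pass along x (stride ny)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) buf[x] = g[lin(y, x, z, ny, nx)];
      dt1d(buf.data(), res.data(), nx, dx);
      for (int x = 0; x < nx; ++x) g[lin(y, x, z, ny, nx)] = res[x];
    }
  // pass along z (stride ny*nx)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) buf[z] = g[lin(y, x, z, ny, nx)];
      dt1d(buf.data(), res.data(), nz, dz);
      for (int z = 0; z < nz; ++z) g[lin(y, x, z, ny, nx)] = res[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Per-slice 2D flood fill: background (FALSE) 4-connected to the slice
// border stays background; enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  LogicalVector out(n);
  std::vector<char> reach((size_t)ny * nx);
  std::vector<int> stack_;
  stack_.reserve((size_t)ny * nx);

  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    stack_.clear();
    const R_xlen_t off = (R_xlen_t)z * ny * nx;
    auto push = [&](int y, int x) {
      int id = y + ny * x;
      if (!reach[id] && !mask[off + id]) {
        reach[id] = 1;
        stack_.push_back(id);
      }
    };
    for (int x = 0; x < nx; ++x) { push(0, x); push(ny - 1, x); }
    for (int y = 0; y < ny; ++y) { push(y, 0); push(y, nx - 1); }
    while (!stack_.empty()) {
      int id = stack_.back();
      stack_.pop_back();
      int x = id / ny, y = id - x * ny;
      if (y > 0) push(y - 1, x);
      if (y < ny - 1) push(y + 1, x);
      if (x > 0) push(y, x - 1);
      if (x < nx - 1) push(y, x + 1);
    }
    for (int id = 0; id < ny * nx; ++id)
      out[off + id] = mask[off + id] || !reach[id];
  }
  return out;
}

// Local median and MAD over a w^3 window with edge-replicated borders.
// Returns a list(median=..., mad=...); w must be odd.
// [[Rcpp::export]]
List cpp_local_median_mad(NumericVector x, IntegerVector dims, int w) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (x.size() != n) stop("x length does not match dims");
  if (w < 1 || w % 2 == 0) stop("window must be odd and >= 1");
  const int r = w / 2;
  NumericVector med(n), mad(n);
  const int m = w * w * w;
  std::vector<double> vals(m), devs(m);
  for (int z = 0; z < nz; ++z)
    for (int xx = 0; xx < nx; ++xx)
      for (int y = 0; y < ny; ++y) {
        int k = 0;
        for (int dz = -r; dz <= r; ++dz) {
          int zz = std::min(std::max(z + dz, 0), nz - 1);
          for (int dx = -r; dx <= r; ++dx) {
            int xc = std::min(std::max(xx + dx, 0), nx - 1);
            for (int dy = -r; dy <= r; ++dy) {
              int yc = std::min(std::max(y + dy, 0), ny - 1);
              vals[k++] = x[lin(yc, xc, zz, ny, nx)];
            }
          }
        }
        std::nth_element(vals.begin(), vals.begin() + m / 2, vals.end());
        double mv = vals[m / 2];
        for (int i = 0; i < m; ++i) devs[i] = std::fabs(vals[i] - mv);
        std::nth_element(devs.begin(), devs.begin() + m / 2, devs.end());
        R_xlen_t id = lin(y, xx, z, ny, nx);
        med[id] = mv;
        mad[id] = devs[m / 2];
      }
  return List::create(_["median"] = med, _["mad"] = mad);
}

// Dijkstra over foreground voxels (26-neighbourhood) with physical step
// lengths scaled by the mean node cost of the two endpoints. sources are
// 0-based linear indices. Returns distances (Inf where unreachable) and
// 0-based parent indices (-1 at sources/unreached).
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector dims,
                  double dy, double dx, double dz,
                  IntegerVector sources, NumericVector node_cost) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  bool use_cost = node_cost.size() == n;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector dist(n, INF);
  IntegerVector parent(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    if (s < 0 || s >= n || !mask[s]) stop("source outside foreground");
    dist[s] = 0.0;
    pq.push(QE(0.0, s));
  }
  const double sp[3] = {dy, dx, dz};
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    int z = u / (ny * nx);
    int rem = u - z * ny * nx;
    int x = rem / ny;
    int y = rem - x * ny;
    double cu = use_cost ? node_cost[u] : 1.0;
    for (int ddz = -1; ddz <= 1; ++ddz) {
      int zz = z + ddz;
      if (zz < 0 || zz >= nz) continue;
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int xx = x + ddx;
        if (xx < 0 || xx >= nx) continue;
        for (int ddy = -1; ddy <= 1; ++ddy) {
          int yy = y + ddy;
          if (yy < 0 || yy >= ny) continue;
          if (ddx == 0 && ddy == 0 && ddz == 0) continue;
          int v = lin(yy, xx, zz, ny, nx);
          if (!mask[v]) continue;
          double step = std::sqrt(ddy * ddy * sp[0] * sp[0] +
                                  ddx * ddx * sp[1] * sp[1] +
                                  ddz * ddz * sp[2] * sp[2]);
          double cv = use_cost ? node_cost[v] : 1.0;
          double nd = dist[u] + step * 0.5 * (cu + cv);
          if (nd < dist[v]) {
            dist[v] = nd;
            parent[v] = u;
            pq.push(QE(nd, v));
          }
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}
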
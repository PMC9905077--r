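#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
// 1D squared distance transform of a sampled function f, result into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in voxel units) from every voxel to the nearest voxel
// where `feature` is TRUE. Voxels with no feature anywhere get Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, int nx, int ny, int nz) {
  // large finite sentinel: infinities break the lower-envelope recursion
  const double INF = 1e20;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) f[x] = g[base + x];
        dt1d(f, d);
        for (int x = 0; x < nx; ++x) g[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
        dt1d(f, d);
        for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nxy];
        dt1d(f, d);
        for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nxy] = d[z];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= 1e19) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// ---- geodesic distance inside a mask (26-connectivity, 1/sqrt2/sqrt3) ----
// [[Rcpp::export]]
NumericVector cpp_geodesic(LogicalVector mask, int nx, int ny, int nz,
                           IntegerVector sources) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n, NA_REAL);
  std::vector<double> d(n, std::numeric_limits<double>::infinity());
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    R_xlen_t idx = sources[s]; // 0-based
    if (idx < 0 || idx >= n || !mask[idx]) stop("source voxel outside mask");
    d[idx] = 0.0;
    pq.push(Node(0.0, idx));
  }
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    if (top.first > d[top.second]) continue;
    R_xlen_t i = top.second;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          R_xlen_t j = (R_xlen_t)Z * nxy + (R_xlen_t)Y * nx + X;
          if (!mask[j]) continue;
          double w = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          if (d[i] + w < d[j]) {
            d[j] = d[i] + w;
            pq.push(Node(d[j], j));
          }
        }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i] && !std::isinf(d[i])) dist[i] = d[i];
  return dist;
}

// ---- connected components, 26-connectivity ----
// [[Rcpp::export]]
IntegerVector cpp_components(LogicalVector mask, int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++cur;
    stack.push_back(seed);
    lab[seed] = cur;
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            R_xlen_t j = (R_xlen_t)Z * nxy + (R_xlen_t)Y * nx + X;
            if (mask[j] && !lab[j]) {
              lab[j] = cur;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}
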
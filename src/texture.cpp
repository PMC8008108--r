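#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gray-level inputs are integer arrays in column-major (R) order with 0
// marking voxels outside the mask; levels inside the mask are >= 1.

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Symmetric GLCM counts for the 13 unique 3D offsets at distance 1.
// Returns ng x ng x 13 array of raw pair counts (each pair counted in both
// orientations, i.e. already symmetric).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li <= 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj <= 0) continue;
          out[(li - 1) + ng * (lj - 1) + ng * ng * d] += 1.0;
          out[(lj - 1) + ng * (li - 1) + ng * ng * d] += 1.0;
        }
      }
    }
  }
  return out;
}

// GLRLM counts per direction: ng x maxrun x 13. A run is a maximal straight
// segment of in-mask voxels sharing one gray level.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li <= 0) continue;
          // run start: predecessor along -d is outside mask/grid or differs
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz) {
            if (levels[idx3(xp, yp, zp, nx, ny)] == li) continue;
          }
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
                 levels[idx3(xn, yn, zn, nx, ny)] == li) {
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          out[(li - 1) + ng * (len - 1) + ng * maxrun * d] += 1.0;
        }
      }
    }
  }
  return out;
}

// 26-connected zones of constant gray level; returns a matrix with one row
// per zone: (gray level, zone size in voxels).
// [[Rcpp::export]]
IntegerMatrix cpp_zones(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] <= 0) continue;
    int lev = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cz = cur / (nx * ny);
      int rem = cur % (nx * ny);
      int cy = rem / nx;
      int cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int j = idx3(x2, y2, z2, nx, ny);
            if (!seen[j] && levels[j] == lev) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}

// NGTDM accumulators: for each gray level i, n_i = number of in-mask voxels
// of level i having at least one in-mask 26-neighbour, s_i = sum over those
// voxels of |i - mean(neighbour levels)|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj > 0) { sum += lj; ++cnt; }
            }
        if (cnt > 0) {
          out(li - 1, 0) += 1.0;
          out(li - 1, 1) += std::fabs((double)li - sum / cnt);
        }
      }
  return out;
}

// GLDM counts: P(i, j) with j = (number of 26-neighbours whose level differs
// from the centre by at most alpha) + 1. Columns 1..27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int ng, int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int lj = levels[idx3(x2, y2, z2, nx, ny)];
              if (lj > 0 && std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// --- exact anisotropic squared Euclidean distance transform ----------------
// Felzenszwalb & Huttenlocher separable lower-envelope pass; w2 is the
// squared physical sample spacing along the scanned axis.
static void edt_pass(std::vector<double> &f, std::vector<double> &d,
                     std::vector<int> &v, std::vector<double> &zbuf,
                     int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      zbuf[0] = -INF;
      zbuf[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zbuf[k]) --k; else break;
      // zbuf[0] = -INF guarantees k never drops below 0
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < (double)q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (double)(q - p) + f[p];
  }
}

// Squared Euclidean distance (physical units) from every voxel to the nearest
// feature voxel (feature != 0). Voxel-centre convention.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(IntegerVector feature, IntegerVector dims,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector D(n);
  for (int i = 0; i < n; ++i) D[i] = feature[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = D[idx3(x, y, z, nx, ny)];
      edt_pass(f, d, v, zbuf, nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; ++x) D[idx3(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = D[idx3(x, y, z, nx, ny)];
      edt_pass(f, d, v, zbuf, ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; ++y) D[idx3(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = D[idx3(x, y, z, nx, ny)];
      edt_pass(f, d, v, zbuf, nz, spacing[2] * spacing[2]);
      for (int z = 0; z < nz; ++z) D[idx3(x, y, z, nx, ny)] = d[z];
    }
  return D;
}

// Geodesic (within-mask) distance from source voxels, propagated over the
// 26-neighbourhood graph with physical edge lengths; voxels with allowed == 0
// block propagation. Chamfer-style approximation of the geodesic metric.
// [[Rcpp::export]]
NumericVector cpp_geodesic_dist(IntegerVector allowed, IntegerVector source,
                                IntegerVector dims, NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector D(n, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < n; ++i)
    if (source[i]) { D[i] = 0.0; pq.push(QE(0.0, i)); }
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    double dist = top.first;
    int cur = top.second;
    if (dist > D[cur]) continue;
    int cz = cur / (nx * ny);
    int rem = cur % (nx * ny);
    int cy = rem / nx;
    int cx = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int j = idx3(x2, y2, z2, nx, ny);
          if (!allowed[j] && !source[j]) continue;
          double step = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                                  dy * dy * spacing[1] * spacing[1] +
                                  dz * dz * spacing[2] * spacing[2]);
          if (D[cur] + step < D[j]) {
            D[j] = D[cur] + step;
            pq.push(QE(D[j], j));
          }
        }
  }
  return D;
}

// 26-connected component labelling of a binary mask; 0 outside.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    stack.clear();
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cz = cur / (nx * ny);
      int rem = cur % (nx * ny);
      int cy = rem / nx;
      int cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int j = idx3(x2, y2, z2, nx, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}
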
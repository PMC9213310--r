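// Exact Euclidean distance transform on anisotropic grids
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas, applied per
// axis with the physical voxel spacing), plus 6-connectivity boundary
// extraction. All distances are between voxel centers, in mm, which is the
// convention every surface metric in the package shares.

#include <Rcpp.h>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled cost f at positions i*s.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 const int n, const double s) {
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    while (true) {
      if (f[v[k]] == INF) { v[k] = q; z[k + 1] = INF; break; }
      const double num = (f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k]);
      const double den = 2.0 * s2 * (q - v[k]);
      const double sx = num / den;
      if (sx <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sx;
      z[k + 1] = INF;
      break;
    }
  }
  if (f[v[0]] == INF) {  // whole line empty
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t N = (std::size_t)nx * ny * nz;
  NumericVector g(N);
  for (std::size_t i = 0; i < N; ++i) g[i] = mask[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const std::size_t base = (std::size_t)nx * (j + (std::size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const std::size_t base = i + (std::size_t)nx * ny * (std::size_t)k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (std::size_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[base + (std::size_t)nx * j] = d[j];
    }
  // z axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const std::size_t base = i + (std::size_t)nx * j;
      const std::size_t str = (std::size_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = g[base + str * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[base + str * k] = d[k];
    }

  for (std::size_t i = 0; i < N; ++i)
    g[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  g.attr("dim") = IntegerVector::create(nx, ny, nz);
  return g;
}

// Boundary voxels: inside the mask with at least one 6-neighbour outside it
// (voxels beyond the volume edge count as outside).

// [[Rcpp::export]]
LogicalVector cpp_boundary6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((std::size_t)nx * ny * nz);
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return mask[i + (std::size_t)nx * (j + (std::size_t)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        const bool b = !at(i - 1, j, k) || !at(i + 1, j, k) ||
                       !at(i, j - 1, k) || !at(i, j + 1, k) ||
                       !at(i, j, k - 1) || !at(i, j, k + 1);
        out[i + (std::size_t)nx * (j + (std::size_t)ny * k)] = b;
      }
  out.attr("dim") = dims;
  return out;
}
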
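// Volume resampling under an affine (here: rigid) physical-space map, and
// brute-force nearest-neighbour correspondence for ICP.
//
// Coordinate convention: voxel (i, j, k) (0-based) sits at physical
// position (i*sx, j*sy, k*sz) mm. The 4x4 matrix A maps a *target* physical
// coordinate to the *source* physical coordinate at which the source volume
// is sampled. Interpolation modes: 0 nearest, 1 trilinear, 3 cubic B-spline
// (with the causal/anticausal prefilter so the spline interpolates the
// samples exactly). Sample points outside the source grid return `bg`.

#include <Rcpp.h>
using namespace Rcpp;

// ---- cubic B-spline prefilter (pole sqrt(3) - 2, mirror boundaries) ----

static void prefilter_line(double* c, const int n, const std::size_t stride) {
  if (n < 2) return;
  const double z = std::sqrt(3.0) - 2.0;  // ~ -0.2679
  const double gain = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) c[(std::size_t)i * stride] *= gain;
  // causal init: truncated sum over the mirrored signal
  const int horizon = std::min(n, (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z))));
  double sum = c[0];
  double zn = z;
  for (int i = 1; i < horizon; ++i) {
    sum += zn * c[(std::size_t)i * stride];
    zn *= z;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i)
    c[(std::size_t)i * stride] += z * c[(std::size_t)(i - 1) * stride];
  // anticausal init (mirror boundary)
  c[(std::size_t)(n - 1) * stride] =
      (z / (z * z - 1.0)) *
      (z * c[(std::size_t)(n - 2) * stride] + c[(std::size_t)(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[(std::size_t)i * stride] =
        z * (c[(std::size_t)(i + 1) * stride] - c[(std::size_t)i * stride]);
}

static void prefilter_volume(std::vector<double>& v, const int nx,
                             const int ny, const int nz) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      prefilter_line(&v[(std::size_t)nx * (j + (std::size_t)ny * k)], nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      prefilter_line(&v[i + (std::size_t)nx * ny * (std::size_t)k], ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      prefilter_line(&v[i + (std::size_t)nx * j], nz, (std::size_t)nx * ny);
}

static inline int mirror_index(int i, const int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = std::abs(i) % period;
  return (i < n) ? i : period - i;
}

static inline void bspline_weights(const double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdims,
                           NumericVector sspacing, IntegerVector ddims,
                           NumericVector dspacing, NumericMatrix A,
                           const int mode, const double bg) {
  const int nx = sdims[0], ny = sdims[1], nz = sdims[2];
  const int mx = ddims[0], my = ddims[1], mz = ddims[2];
  const double sx = sspacing[0], sy = sspacing[1], sz = sspacing[2];

  std::vector<double> coef;
  const double* data = src.begin();
  if (mode == 3) {
    coef.assign(src.begin(), src.end());
    prefilter_volume(coef, nx, ny, nz);
    data = coef.data();
  }

  NumericVector out((std::size_t)mx * my * mz);
  auto val = [&](int i, int j, int k) -> double {
    return data[mirror_index(i, nx) +
                (std::size_t)nx * (mirror_index(j, ny) +
                                   (std::size_t)ny * mirror_index(k, nz))];
  };

  std::size_t o = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++o) {
        const double px = i * dspacing[0], py = j * dspacing[1],
                     pz = k * dspacing[2];
        const double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + A(0, 3);
        const double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + A(1, 3);
        const double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + A(2, 3);
        const double u = qx / sx, v = qy / sy, w = qz / sz;
        const double eps = 1e-9;
        if (u < -eps || u > nx - 1 + eps || v < -eps || v > ny - 1 + eps ||
            w < -eps || w > nz - 1 + eps) {
          out[o] = bg;
          continue;
        }
        if (mode == 0) {
          const int iu = (int)std::lround(u), iv = (int)std::lround(v),
                    iw = (int)std::lround(w);
          out[o] = val(iu, iv, iw);
        } else if (mode == 1) {
          const int iu = (int)std::floor(u), iv = (int)std::floor(v),
                    iw = (int)std::floor(w);
          const double fu = u - iu, fv = v - iv, fw = w - iw;
          double acc = 0.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double wt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) *
                                  (dk ? fw : 1 - fw);
                if (wt != 0.0) acc += wt * val(iu + di, iv + dj, iw + dk);
              }
          out[o] = acc;
        } else {
          const int iu = (int)std::floor(u), iv = (int)std::floor(v),
                    iw = (int)std::floor(w);
          double wu[4], wv[4], ww[4];
          bspline_weights(u - iu, wu);
          bspline_weights(v - iv, wv);
          bspline_weights(w - iw, ww);
          double acc = 0.0;
          for (int dk = 0; dk < 4; ++dk)
            for (int dj = 0; dj < 4; ++dj)
              for (int di = 0; di < 4; ++di)
                acc += wu[di] * wv[dj] * ww[dk] *
                       val(iu - 1 + di, iv - 1 + dj, iw - 1 + dk);
          out[o] = acc;
        }
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}

// Nearest fixed point for every moving point; ties break to the lowest
// fixed-point index. Rows are points, columns x/y/z in mm.

// [[Rcpp::export]]
List cpp_nearest_neighbours(NumericMatrix moving, NumericMatrix fixed) {
  const int n = moving.nrow(), m = fixed.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double px = moving(i, 0), py = moving(i, 1), pz = moving(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = fixed(j, 0) - px, dy = fixed(j, 1) - py,
                   dz = fixed(j, 2) - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
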
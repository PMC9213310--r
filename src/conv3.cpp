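// 3D convolution primitives for the patch-based UNet.
//
// Volumes are column-major R arrays dim (nx, ny, nz, C); a (nx*ny*nz) x C
// matrix view is therefore free. Convolutions are 3x3x3, stride 1, zero
// "same" padding, expressed as im2col followed by a GEMM so BLAS does the
// heavy lifting. The patch matrix is laid out N x K (voxels x features) so
// every fill/scatter runs over contiguous memory. Weights live in R as a
// (27*Cin) x Cout matrix whose row order is tap-major within channel:
// r = t + 27*c with t = (di+1) + 3*(dj+1) + 9*(dk+1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill column r of the N x K patch matrix for tap t of channel c.
static void fill_patch_col(double* colr, const double* xc, const int nx,
                           const int ny, const int nz, const int t) {
  const int di = t % 3 - 1;
  const int dj = (t / 3) % 3 - 1;
  const int dk = t / 9 - 1;
  for (int k = 0; k < nz; ++k) {
    const int ks = k + dk;
    if (ks < 0 || ks >= nz) continue;
    for (int j = 0; j < ny; ++j) {
      const int js = j + dj;
      if (js < 0 || js >= ny) continue;
      const int i0 = std::max(0, -di);
      const int i1 = std::min(nx, nx - di);
      const double* src = xc + di + (std::size_t)nx * (js + (std::size_t)ny * ks);
      double* dst = colr + (std::size_t)nx * (j + (std::size_t)ny * k);
      for (int i = i0; i < i1; ++i) dst[i] = src[i];
    }
  }
}

static arma::mat im2col3(const double* x, const int nx, const int ny,
                         const int nz, const int cin) {
  const std::size_t N = (std::size_t)nx * ny * nz;
  arma::mat col(N, 27 * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int t = 0; t < 27; ++t)
      fill_patch_col(col.colptr(t + 27 * c), x + N * c, nx, ny, nz, t);
  return col;
}

// Scatter-add column r (tap t, channel c) back into the gradient volume.
static void col2im3(const arma::mat& col, double* gx, const int nx,
                    const int ny, const int nz, const int cin) {
  const std::size_t N = (std::size_t)nx * ny * nz;
  std::fill(gx, gx + N * cin, 0.0);
  for (int c = 0; c < cin; ++c) {
    double* xc = gx + N * c;
    for (int t = 0; t < 27; ++t) {
      const int di = t % 3 - 1;
      const int dj = (t / 3) % 3 - 1;
      const int dk = t / 9 - 1;
      const double* colr = col.colptr(t + 27 * c);
      for (int k = 0; k < nz; ++k) {
        const int ks = k + dk;
        if (ks < 0 || ks >= nz) continue;
        for (int j = 0; j < ny; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= ny) continue;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(nx, nx - di);
          double* dst = xc + di + (std::size_t)nx * (js + (std::size_t)ny * ks);
          const double* src = colr + (std::size_t)nx * (j + (std::size_t)ny * k);
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_forward(NumericVector x, NumericMatrix w,
                                NumericVector b, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const std::size_t N = (std::size_t)nx * ny * nz;
  const int cout = w.ncol();
  if (w.nrow() != 27 * cin) stop("weight rows must be 27*cin");
  if (b.size() != cout) stop("bias length must equal cout");
  const arma::mat col = im2col3(x.begin(), nx, ny, nz, cin);
  const arma::mat wm(const_cast<double*>(w.begin()), 27 * cin, cout, false);
  arma::mat y = col * wm;  // N x cout
  y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), cout, false);
  NumericVector out(y.memptr(), y.memptr() + N * cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_backward(NumericVector x, NumericMatrix w, NumericVector gy,
                        IntegerVector dims, const bool need_gx = true) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const std::size_t N = (std::size_t)nx * ny * nz;
  const int cout = w.ncol();
  const arma::mat col = im2col3(x.begin(), nx, ny, nz, cin);
  const arma::mat wm(const_cast<double*>(w.begin()), 27 * cin, cout, false);
  const arma::mat gym(const_cast<double*>(gy.begin()), N, cout, false);

  arma::mat gw = col.t() * gym;        // K x cout (BLAS handles the transpose)
  arma::rowvec gb = arma::sum(gym, 0);

  NumericMatrix gwR(27 * cin, cout);
  std::copy(gw.memptr(), gw.memptr() + gw.n_elem, gwR.begin());
  NumericVector gbR(cout);
  std::copy(gb.memptr(), gb.memptr() + cout, gbR.begin());

  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gwR, _["gb"] = gbR);

  arma::mat gcol = gym * wm.t();       // N x K
  NumericVector gx(N * cin);
  col2im3(gcol, gx.begin(), nx, ny, nz, cin);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["gx"] = gx, _["gw"] = gwR, _["gb"] = gbR);
}

// 2x2x2 max pooling, stride 2. Input dims must be even. Returns the pooled
// volume and the 0-based linear index (into the input) of each maximum so
// the backward pass is an exact scatter. Ties resolve to the first voxel in
// column-major order, which keeps the op deterministic.

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("pooling needs even spatial dims");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const std::size_t N = (std::size_t)nx * ny * nz;
  const std::size_t M = (std::size_t)ox * oy * oz;
  NumericVector y(M * C);
  IntegerVector idx(M * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bestIdx = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const std::size_t ii = (2 * i + di) +
                    (std::size_t)nx * ((2 * j + dj) + (std::size_t)ny * (2 * k + dk));
                if (xc[ii] > best) { best = xc[ii]; bestIdx = ii; }
              }
          const std::size_t o = i + (std::size_t)ox * (j + (std::size_t)oy * k) + M * c;
          y[o] = best;
          idx[o] = (int)(bestIdx + N * c);
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  idx.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector in_dims) {
  const std::size_t N = (std::size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector gx(N);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = in_dims;
  return gx;
}
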
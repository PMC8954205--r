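#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// mirror (half-sample symmetric) index: ... c b a | a b c ... | c b a
static inline int mirror_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 2-D "same" convolution with symmetric boundary padding.
// The kernel is flipped, i.e. true convolution; Gaussian PSFs are symmetric
// so this coincides with correlation for them. Rank-1 kernels (all Gaussian
// PSFs are outer products of 1-D Gaussians) take a separable two-pass path;
// mirroring acts per axis, so the result is identical up to rounding.
// [[Rcpp::export]]
NumericMatrix cpp_conv2d_sym(const NumericMatrix& x, const NumericMatrix& k) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = k.nrow(), kc = k.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);

  // rank-1 test: k(a,b) == r[a] * c[b] anchored at the largest element
  int am = 0, bm = 0;
  double kmax = 0.0;
  for (int b = 0; b < kc; ++b)
    for (int a = 0; a < kr; ++a)
      if (std::abs(k(a, b)) > kmax) { kmax = std::abs(k(a, b)); am = a; bm = b; }
  bool sep = kmax > 0.0;
  std::vector<double> rfac(kr), cfac(kc);
  if (sep) {
    for (int a = 0; a < kr; ++a) rfac[a] = k(a, bm);
    for (int b = 0; b < kc; ++b) cfac[b] = k(am, b) / k(am, bm);
    for (int b = 0; b < kc && sep; ++b)
      for (int a = 0; a < kr; ++a)
        if (std::abs(k(a, b) - rfac[a] * cfac[b]) > 1e-12 * kmax) {
          sep = false;
          break;
        }
  }

  if (sep) {
    NumericMatrix tmp(nr, nc);  // vertical pass with r, then horizontal with c
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double acc = 0.0;
        for (int a = 0; a < kr; ++a)
          acc += rfac[a] * x(mirror_idx(i + hr - a, nr), j);
        tmp(i, j) = acc;
      }
    for (int j = 0; j < nc; ++j)
      for (int b = 0; b < kc; ++b) {
        const int jj = mirror_idx(j + hc - b, nc);
        const double cb = cfac[b];
        for (int i = 0; i < nr; ++i) out(i, j) += cb * tmp(i, jj);
      }
    return out;
  }

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kc; ++b) {
        const int jj = mirror_idx(j + hc - b, nc);
        for (int a = 0; a < kr; ++a) {
          const int ii = mirror_idx(i + hr - a, nr);
          acc += k(a, b) * x(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Local median and population variance over a w x w window (w odd),
// symmetric boundary padding. Returns list(median=, var=).
// [[Rcpp::export]]
List cpp_local_median_var(const NumericMatrix& x, int w) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = w / 2, m = w * w;
  NumericMatrix med(nr, nc), var(nr, nc);
  std::vector<double> buf(m);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      int t = 0;
      for (int b = -h; b <= h; ++b) {
        const int jj = mirror_idx(j + b, nc);
        for (int a = -h; a <= h; ++a) {
          const double v = x(mirror_idx(i + a, nr), jj);
          buf[t++] = v;
          s += v;
          s2 += v * v;
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double md = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.end());
        md = 0.5 * (md + buf[m / 2 - 1]);
      }
      med(i, j) = md;
      const double mu = s / m;
      double v2 = s2 / m - mu * mu;
      var(i, j) = v2 > 0 ? v2 : 0.0;
    }
  }
  return List::create(_["median"] = med, _["var"] = var);
}

static inline int conv_out_dim(int d, int k, int stride, int pad) {
  return (d + 2 * pad - k) / stride + 1;
}

// Unfold a 4-D array [d1,d2,d3,cin] (column-major) into an im2col matrix
// [n_out_voxels, k^3 * cin] for a cubic kernel with given stride and
// zero padding. Row order: output voxels in column-major (o1 fastest);
// column order: (k1, k2, k3, c) column-major.
// [[Rcpp::export]]
NumericMatrix cpp_vol2col(const NumericVector& x, const IntegerVector& dims,
                          int k, int stride, int pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int o1 = conv_out_dim(d1, k, stride, pad);
  const int o2 = conv_out_dim(d2, k, stride, pad);
  const int o3 = conv_out_dim(d3, k, stride, pad);
  const int nout = o1 * o2 * o3;
  NumericMatrix cols(nout, k * k * k * cin);
  const double* px = x.begin();
  for (int c = 0; c < cin; ++c) {
    const double* pc = px + (R_xlen_t)c * d1 * d2 * d3;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const int col = ((c * k + k3) * k + k2) * k + k1;
          double* pdst = &cols(0, col);
          for (int z = 0; z < o3; ++z) {
            const int iz = z * stride - pad + k3;
            const bool okz = iz >= 0 && iz < d3;
            for (int y = 0; y < o2; ++y) {
              const int iy = y * stride - pad + k2;
              const bool oky = okz && iy >= 0 && iy < d2;
              const R_xlen_t row0 = ((R_xlen_t)z * o2 + y) * o1;
              if (!oky) continue;  // cols initialised to 0
              const double* psrc = pc + ((R_xlen_t)iz * d2 + iy) * d1;
              for (int xo = 0; xo < o1; ++xo) {
                const int ix = xo * stride - pad + k1;
                if (ix >= 0 && ix < d1) pdst[row0 + xo] = psrc[ix];
              }
            }
          }
        }
  }
  return cols;
}

// Adjoint of cpp_vol2col: scatter-add column gradients back to the input
// grid. Returns a vector of length prod(dims) shaped [d1,d2,d3,cin].
// [[Rcpp::export]]
NumericVector cpp_col2vol(const NumericMatrix& cols, const IntegerVector& dims,
                          int k, int stride, int pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int o1 = conv_out_dim(d1, k, stride, pad);
  const int o2 = conv_out_dim(d2, k, stride, pad);
  const int o3 = conv_out_dim(d3, k, stride, pad);
  NumericVector out((R_xlen_t)d1 * d2 * d3 * cin);
  double* po = out.begin();
  for (int c = 0; c < cin; ++c) {
    double* pc = po + (R_xlen_t)c * d1 * d2 * d3;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const int col = ((c * k + k3) * k + k2) * k + k1;
          const double* psrc = &cols(0, col);
          for (int z = 0; z < o3; ++z) {
            const int iz = z * stride - pad + k3;
            if (iz < 0 || iz >= d3) continue;
            for (int y = 0; y < o2; ++y) {
              const int iy = y * stride - pad + k2;
              if (iy < 0 || iy >= d2) continue;
              const R_xlen_t row0 = ((R_xlen_t)z * o2 + y) * o1;
              double* pdst = pc + ((R_xlen_t)iz * d2 + iy) * d1;
              for (int xo = 0; xo < o1; ++xo) {
                const int ix = xo * stride - pad + k1;
                if (ix >= 0 && ix < d1) pdst[ix] += psrc[row0 + xo];
              }
            }
          }
        }
  }
  return out;
}

// 3-D max pooling over [d1,d2,d3,C] with cubic window, stride and zero
// padding (padded cells never win). Returns pooled values and the 1-based
// linear argmax index into the input for backprop.
// [[Rcpp::export]]
List cpp_maxpool3d(const NumericVector& x, const IntegerVector& dims,
                   int k, int stride, int pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  const int o1 = conv_out_dim(d1, k, stride, pad);
  const int o2 = conv_out_dim(d2, k, stride, pad);
  const int o3 = conv_out_dim(d3, k, stride, pad);
  const R_xlen_t nout = (R_xlen_t)o1 * o2 * o3 * C;
  NumericVector y(nout);
  IntegerVector arg(nout);
  const double* px = x.begin();
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c) {
    const double* pc = px + (R_xlen_t)c * d1 * d2 * d3;
    for (int z = 0; z < o3; ++z)
      for (int yy = 0; yy < o2; ++yy)
        for (int xx = 0; xx < o1; ++xx, ++t) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int k3 = 0; k3 < k; ++k3) {
            const int iz = z * stride - pad + k3;
            if (iz < 0 || iz >= d3) continue;
            for (int k2 = 0; k2 < k; ++k2) {
              const int iy = yy * stride - pad + k2;
              if (iy < 0 || iy >= d2) continue;
              for (int k1 = 0; k1 < k; ++k1) {
                const int ix = xx * stride - pad + k1;
                if (ix < 0 || ix >= d1) continue;
                const R_xlen_t li = ((R_xlen_t)iz * d2 + iy) * d1 + ix;
                const double v = pc[li];
                if (v > best) { best = v; bi = li; }
              }
            }
          }
          y[t] = best;
          arg[t] = (int)(bi + (R_xlen_t)c * d1 * d2 * d3) + 1;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg,
                      _["odims"] = IntegerVector::create(o1, o2, o3, C));
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(const NumericVector& dy,
                                const IntegerVector& argmax, int xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}

// Trilinear resampling of a 3-D array to new dims (align-corners mapping;
// a singleton output axis samples the centre of the input axis).
// [[Rcpp::export]]
NumericVector cpp_resample3d(const NumericVector& x, const IntegerVector& dims,
                             const IntegerVector& newdims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n1 = newdims[0], n2 = newdims[1], n3 = newdims[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  const double* px = x.begin();
  auto src = [&](int axis_n, int axis_d, int i) -> double {
    if (axis_n == 1) return 0.5 * (axis_d - 1);
    return (double)i * (axis_d - 1) / (axis_n - 1);
  };
  R_xlen_t t = 0;
  for (int z = 0; z < n3; ++z) {
    const double fz = src(n3, d3, z);
    const int z0 = (int)std::floor(fz), z1 = std::min(z0 + 1, d3 - 1);
    const double wz = fz - z0;
    for (int y = 0; y < n2; ++y) {
      const double fy = src(n2, d2, y);
      const int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, d2 - 1);
      const double wy = fy - y0;
      for (int xx = 0; xx < n1; ++xx, ++t) {
        const double fx = src(n1, d1, xx);
        const int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, d1 - 1);
        const double wx = fx - x0;
        auto at = [&](int a, int b, int c) {
          return px[((R_xlen_t)c * d2 + b) * d1 + a];
        };
        const double c00 = at(x0, y0, z0) * (1 - wx) + at(x1, y0, z0) * wx;
        const double c10 = at(x0, y1, z0) * (1 - wx) + at(x1, y1, z0) * wx;
        const double c01 = at(x0, y0, z1) * (1 - wx) + at(x1, y0, z1) * wx;
        const double c11 = at(x0, y1, z1) * (1 - wx) + at(x1, y1, z1) * wx;
        const double c0 = c00 * (1 - wy) + c10 * wy;
        const double c1 = c01 * (1 - wy) + c11 * wy;
        out[t] = c0 * (1 - wz) + c1 * wz;
      }
    }
  }
  return out;
}

// ---- small column-wise helpers for batch normalisation ----

// (A - m[j]) * s[j]
// [[Rcpp::export]]
NumericMatrix cpp_center_scale(const NumericMatrix& A, const NumericVector& m,
                               const NumericVector& s) {
  const int nr = A.nrow(), nc = A.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double mj = m[j], sj = s[j];
    for (int i = 0; i < nr; ++i) out(i, j) = (A(i, j) - mj) * sj;
  }
  return out;
}

// A * g[j] + b[j]
// [[Rcpp::export]]
NumericMatrix cpp_scale_shift(const NumericMatrix& A, const NumericVector& g,
                              const NumericVector& b) {
  const int nr = A.nrow(), nc = A.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double gj = g[j], bj = b[j];
    for (int i = 0; i < nr; ++i) out(i, j) = A(i, j) * gj + bj;
  }
  return out;
}

// (N * dxhat - t1[j] - xhat * t2[j]) * w[j]   (w = invstd / N)
// [[Rcpp::export]]
NumericMatrix cpp_bn_dx(const NumericMatrix& dxhat, const NumericMatrix& xhat,
                        const NumericVector& t1, const NumericVector& t2,
                        const NumericVector& w) {
  const int nr = dxhat.nrow(), nc = dxhat.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double t1j = t1[j], t2j = t2[j], wj = w[j];
    for (int i = 0; i < nr; ++i)
      out(i, j) = (nr * dxhat(i, j) - t1j - xhat(i, j) * t2j) * wj;
  }
  return out;
}
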
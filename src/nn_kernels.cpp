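// Low-level volumetric CNN kernels.
//
// Tensor layout: channel-first column-major R arrays, dim = c(C, X, Y, Z),
// linear index c + C*(x + X*(y + Y*z)).  Convolution weights have
// dim = c(Cout, Cin, k, k, k) so the output-channel index is fastest,
// keeping the inner accumulation loops contiguous.  All kernels are
// single-threaded and bit-deterministic.

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t vox(R_xlen_t C, R_xlen_t X, R_xlen_t Y,
                           R_xlen_t x, R_xlen_t y, R_xlen_t z) {
  return C * (x + X * (y + Y * z));
}

// 3D convolution, odd kernel k, "same" zero padding p = (k-1)/2, stride 1.
// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector b,
                             int k) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Co = b.size();
  const int p = (k - 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(Co) * X * Y * Z);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();

  for (int z = 0; z < Z; ++z)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        double *yo = py + vox(Co, X, Y, ix, iy, z);
        for (int c = 0; c < Co; ++c) yo[c] = pb[c];
        for (int kz = 0; kz < k; ++kz) {
          int sz = z + kz - p; if (sz < 0 || sz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            int sy = iy + ky - p; if (sy < 0 || sy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              int sx = ix + kx - p; if (sx < 0 || sx >= X) continue;
              const double *xi = px + vox(Ci, X, Y, sx, sy, sz);
              const double *wk = pw + static_cast<R_xlen_t>(Co) * Ci *
                                 (kx + k * (ky + k * kz));
              for (int ci = 0; ci < Ci; ++ci) {
                const double xv = xi[ci];
                if (xv == 0.0) continue;
                const double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                for (int c = 0; c < Co; ++c) yo[c] += wc[c] * xv;
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(Co, X, Y, Z);
  return y;
}

// Gradient w.r.t. the input of conv3d_forward.
// [[Rcpp::export(name = ".conv3d_backward_x")]]
NumericVector conv3d_backward_x(NumericVector gy, IntegerVector xdim,
                                NumericVector w, int k, int Co) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int p = (k - 1) / 2;
  NumericVector gx(static_cast<R_xlen_t>(Ci) * X * Y * Z);
  const double *pg = gy.begin(), *pw = w.begin();
  double *pgx = gx.begin();

  // y[o] = sum_k x[o + k - p] w[k]  =>  gx[i] = sum_k gy[i - k + p] w[k]
  for (int z = 0; z < Z; ++z)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        double *gi = pgx + vox(Ci, X, Y, ix, iy, z);
        for (int kz = 0; kz < k; ++kz) {
          int oz = z - kz + p; if (oz < 0 || oz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            int oy = iy - ky + p; if (oy < 0 || oy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              int ox = ix - kx + p; if (ox < 0 || ox >= X) continue;
              const double *go = pg + vox(Co, X, Y, ox, oy, oz);
              const double *wk = pw + static_cast<R_xlen_t>(Co) * Ci *
                                 (kx + k * (ky + k * kz));
              for (int ci = 0; ci < Ci; ++ci) {
                const double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                double acc = 0.0;
                for (int c = 0; c < Co; ++c) acc += wc[c] * go[c];
                gi[ci] += acc;
              }
            }
          }
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// Gradients w.r.t. weights and bias of conv3d_forward.
// [[Rcpp::export(name = ".conv3d_backward_w")]]
List conv3d_backward_w(NumericVector x, IntegerVector xdim,
                       NumericVector gy, int k, int Co) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int p = (k - 1) / 2;
  NumericVector gw(static_cast<R_xlen_t>(Co) * Ci * k * k * k);
  NumericVector gb(Co);
  const double *px = x.begin(), *pg = gy.begin();
  double *pgw = gw.begin(), *pgb = gb.begin();

  for (int z = 0; z < Z; ++z)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        const double *go = pg + vox(Co, X, Y, ix, iy, z);
        for (int c = 0; c < Co; ++c) pgb[c] += go[c];
        for (int kz = 0; kz < k; ++kz) {
          int sz = z + kz - p; if (sz < 0 || sz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            int sy = iy + ky - p; if (sy < 0 || sy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              int sx = ix + kx - p; if (sx < 0 || sx >= X) continue;
              const double *xi = px + vox(Ci, X, Y, sx, sy, sz);
              double *wk = pgw + static_cast<R_xlen_t>(Co) * Ci *
                           (kx + k * (ky + k * kz));
              for (int ci = 0; ci < Ci; ++ci) {
                const double xv = xi[ci];
                if (xv == 0.0) continue;
                double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                for (int c = 0; c < Co; ++c) wc[c] += go[c] * xv;
              }
            }
          }
        }
      }
  gw.attr("dim") = IntegerVector::create(Co, Ci, k, k, k);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2.  Spatial dims must be even.
// Returns the pooled tensor and 1-based argmax indices into the input.
// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y(static_cast<R_xlen_t>(C) * Xo * Yo * Zo);
  IntegerVector amax(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = amax.begin();

  R_xlen_t o = 0;
  for (int z = 0; z < Zo; ++z)
    for (int iy = 0; iy < Yo; ++iy)
      for (int ix = 0; ix < Xo; ++ix)
        for (int c = 0; c < C; ++c, ++o) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t ii = c + vox(C, X, Y, 2 * ix + dx, 2 * iy + dy,
                                      2 * z + dz);
                if (px[ii] > best) { best = px[ii]; bi = ii; }
              }
          py[o] = best;
          pa[o] = static_cast<int>(bi + 1);
        }
  y.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward(NumericVector gy, IntegerVector argmax,
                                 IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  const double *pg = gy.begin();
  const int *pa = argmax.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) pgx[pa[i] - 1] += pg[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Transposed convolution, kernel 2, stride 2 (learned 2x upsampling).
// w dim = c(Cout, Cin, 2, 2, 2); output spatial dims are doubled.
// [[Rcpp::export(name = ".convt3d_forward")]]
NumericVector convt3d_forward(NumericVector x, IntegerVector xdim,
                              NumericVector w, NumericVector b) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Co = b.size();
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y(static_cast<R_xlen_t>(Co) * Xo * Yo * Zo);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) py[i] = pb[i % Co];

  for (int z = 0; z < Z; ++z)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        const double *xi = px + vox(Ci, X, Y, ix, iy, z);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double *yo = py + vox(Co, Xo, Yo, 2 * ix + dx, 2 * iy + dy,
                                    2 * z + dz);
              const double *wk = pw + static_cast<R_xlen_t>(Co) * Ci *
                                 (dx + 2 * (dy + 2 * dz));
              for (int ci = 0; ci < Ci; ++ci) {
                const double xv = xi[ci];
                if (xv == 0.0) continue;
                const double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                for (int c = 0; c < Co; ++c) yo[c] += wc[c] * xv;
              }
            }
      }
  y.attr("dim") = IntegerVector::create(Co, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export(name = ".convt3d_backward_x")]]
NumericVector convt3d_backward_x(NumericVector gy, IntegerVector xdim,
                                 NumericVector w, int Co) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = 2 * X, Yo = 2 * Y;
  NumericVector gx(static_cast<R_xlen_t>(Ci) * X * Y * Z);
  const double *pg = gy.begin(), *pw = w.begin();
  double *pgx = gx.begin();

  for (int z = 0; z < Z; ++z)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        double *gi = pgx + vox(Ci, X, Y, ix, iy, z);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double *go = pg + vox(Co, Xo, Yo, 2 * ix + dx,
                                          2 * iy + dy, 2 * z + dz);
              const double *wk = pw + static_cast<R_xlen_t>(Co) * Ci *
                                 (dx + 2 * (dy + 2 * dz));
              for (int ci = 0; ci < Ci; ++ci) {
                const double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                double acc = 0.0;
                for (int c = 0; c < Co; ++c) acc += wc[c] * go[c];
                gi[ci] += acc;
              }
            }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export(name = ".convt3d_backward_w")]]
List convt3d_backward_w(NumericVector x, IntegerVector xdim,
                        NumericVector gy, int Co) {
  const int Ci = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = 2 * X, Yo = 2 * Y;
  NumericVector gw(static_cast<R_xlen_t>(Co) * Ci * 8);
  NumericVector gb(Co);
  const double *px = x.begin(), *pg = gy.begin();
  double *pgw = gw.begin(), *pgb = gb.begin();

  for (R_xlen_t i = 0; i < gy.size(); ++i) pgb[i % Co] += pg[i];
  for (int z = 0; z < Z; ++z)
    for (int iy = 0; iy < Y; ++iy)
      for (int ix = 0; ix < X; ++ix) {
        const double *xi = px + vox(Ci, X, Y, ix, iy, z);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double *go = pg + vox(Co, Xo, Yo, 2 * ix + dx,
                                          2 * iy + dy, 2 * z + dz);
              double *wk = pgw + static_cast<R_xlen_t>(Co) * Ci *
                           (dx + 2 * (dy + 2 * dz));
              for (int ci = 0; ci < Ci; ++ci) {
                const double xv = xi[ci];
                if (xv == 0.0) continue;
                double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                for (int c = 0; c < Co; ++c) wc[c] += go[c] * xv;
              }
            }
      }
  gw.attr("dim") = IntegerVector::create(Co, Ci, 2, 2, 2);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
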
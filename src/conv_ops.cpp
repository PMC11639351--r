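#include <Rcpp.h>
using namespace Rcpp;

// Dense 3D convolution kernels.
//
// Layout conventions (match the R side):
//   feature map x : dim (C, X, Y, Z), channel fastest (column-major R array)
//   conv weight w : dim (Cout, Cin/groups, kx, ky, kz)
//   transposed-conv weight w : dim (Cin, Cout, s, s, s) with kernel == stride == s
//
// All loops are channel-innermost so reads/writes stay contiguous.

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector b,
                             IntegerVector kern, IntegerVector stride,
                             IntegerVector pad, int groups) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int kx = kern[0], ky = kern[1], kz = kern[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int Cout = b.size();
  const int Cg = C / groups;        // input channels per group
  const int Cog = Cout / groups;    // output channels per group
  const int Xo = out_size(X, kx, sx, px);
  const int Yo = out_size(Y, ky, sy, py);
  const int Zo = out_size(Z, kz, sz, pz);

  NumericVector y(static_cast<R_xlen_t>(Cout) * Xo * Yo * Zo);
  double *yp = y.begin();
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();

  for (int oz = 0; oz < Zo; ++oz)
  for (int oy = 0; oy < Yo; ++oy)
  for (int ox = 0; ox < Xo; ++ox) {
    double *yv = yp + static_cast<R_xlen_t>(Cout) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
    for (int co = 0; co < Cout; ++co) yv[co] = bp[co];
    for (int dz = 0; dz < kz; ++dz) {
      const int iz = oz * sz - pz + dz;
      if (iz < 0 || iz >= Z) continue;
      for (int dy = 0; dy < ky; ++dy) {
        const int iy = oy * sy - py + dy;
        if (iy < 0 || iy >= Y) continue;
        for (int dx = 0; dx < kx; ++dx) {
          const int ix = ox * sx - px + dx;
          if (ix < 0 || ix >= X) continue;
          const double *xv = xp + static_cast<R_xlen_t>(C) * (ix + static_cast<R_xlen_t>(X) * (iy + static_cast<R_xlen_t>(Y) * iz));
          const double *wk = wp + static_cast<R_xlen_t>(Cout) * Cg * (dx + static_cast<R_xlen_t>(kx) * (dy + static_cast<R_xlen_t>(ky) * dz));
          for (int g = 0; g < groups; ++g) {
            for (int cl = 0; cl < Cg; ++cl) {
              const double xval = xv[g * Cg + cl];
              const double *wc = wk + static_cast<R_xlen_t>(Cout) * cl + g * Cog;
              double *yg = yv + g * Cog;
              for (int co = 0; co < Cog; ++co) yg[co] += wc[co] * xval;
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, NumericVector gy,
                    IntegerVector kern, IntegerVector stride,
                    IntegerVector pad, int groups, int Cout) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int kx = kern[0], ky = kern[1], kz = kern[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int Cg = C / groups, Cog = Cout / groups;
  const int Xo = out_size(X, kx, sx, px);
  const int Yo = out_size(Y, ky, sy, py);
  const int Zo = out_size(Z, kz, sz, pz);

  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  double *gxp = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();
  const double *xp = x.begin(), *wp = w.begin(), *gyp = gy.begin();

  for (int oz = 0; oz < Zo; ++oz)
  for (int oy = 0; oy < Yo; ++oy)
  for (int ox = 0; ox < Xo; ++ox) {
    const double *gyv = gyp + static_cast<R_xlen_t>(Cout) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
    for (int co = 0; co < Cout; ++co) gbp[co] += gyv[co];
    for (int dz = 0; dz < kz; ++dz) {
      const int iz = oz * sz - pz + dz;
      if (iz < 0 || iz >= Z) continue;
      for (int dy = 0; dy < ky; ++dy) {
        const int iy = oy * sy - py + dy;
        if (iy < 0 || iy >= Y) continue;
        for (int dx = 0; dx < kx; ++dx) {
          const int ix = ox * sx - px + dx;
          if (ix < 0 || ix >= X) continue;
          const R_xlen_t xoff = static_cast<R_xlen_t>(C) * (ix + static_cast<R_xlen_t>(X) * (iy + static_cast<R_xlen_t>(Y) * iz));
          const R_xlen_t woff = static_cast<R_xlen_t>(Cout) * Cg * (dx + static_cast<R_xlen_t>(kx) * (dy + static_cast<R_xlen_t>(ky) * dz));
          for (int g = 0; g < groups; ++g) {
            for (int cl = 0; cl < Cg; ++cl) {
              const int ci = g * Cg + cl;
              const double xval = xp[xoff + ci];
              const double *wc = wp + woff + static_cast<R_xlen_t>(Cout) * cl + g * Cog;
              double *gwc = gwp + woff + static_cast<R_xlen_t>(Cout) * cl + g * Cog;
              const double *gyg = gyv + g * Cog;
              double acc = 0.0;
              for (int co = 0; co < Cog; ++co) {
                const double gval = gyg[co];
                acc += wc[co] * gval;
                gwc[co] += xval * gval;
              }
              gxp[xoff + ci] += acc;
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution with kernel == stride == s (non-overlapping upsampling):
// y[co, s*x+i, s*y+j, s*z+k] = b[co] + sum_ci x[ci, x,y,z] * w[ci, co, i,j,k]

// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector w, NumericVector b, int s) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Cout = b.size();
  const int Xo = X * s, Yo = Y * s, Zo = Z * s;
  NumericVector y(static_cast<R_xlen_t>(Cout) * Xo * Yo * Zo);
  double *yp = y.begin();
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();

  for (int z = 0; z < Z; ++z)
  for (int yy = 0; yy < Y; ++yy)
  for (int xx = 0; xx < X; ++xx) {
    const double *xv = xp + static_cast<R_xlen_t>(C) * (xx + static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * z));
    for (int k = 0; k < s; ++k)
    for (int j = 0; j < s; ++j)
    for (int i = 0; i < s; ++i) {
      const int ox = s * xx + i, oy = s * yy + j, oz = s * z + k;
      double *yv = yp + static_cast<R_xlen_t>(Cout) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
      const double *wk = wp + static_cast<R_xlen_t>(C) * Cout * (i + static_cast<R_xlen_t>(s) * (j + static_cast<R_xlen_t>(s) * k));
      for (int co = 0; co < Cout; ++co) {
        double acc = bp[co];
        const double *wc = wk + co * static_cast<R_xlen_t>(C) * 1; // w[ci, co, ...]: ci fastest
        for (int ci = 0; ci < C; ++ci) acc += xv[ci] * wc[ci];
        yv[co] += acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, IntegerVector xdim,
                     NumericVector w, NumericVector gy, int s, int Cout) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int Xo = X * s, Yo = Y * s, Zo = Z * s;
  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  double *gxp = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();
  const double *xp = x.begin(), *wp = w.begin(), *gyp = gy.begin();

  for (int z = 0; z < Z; ++z)
  for (int yy = 0; yy < Y; ++yy)
  for (int xx = 0; xx < X; ++xx) {
    const R_xlen_t xoff = static_cast<R_xlen_t>(C) * (xx + static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * z));
    for (int k = 0; k < s; ++k)
    for (int j = 0; j < s; ++j)
    for (int i = 0; i < s; ++i) {
      const int ox = s * xx + i, oy = s * yy + j, oz = s * z + k;
      const double *gyv = gyp + static_cast<R_xlen_t>(Cout) * (ox + static_cast<R_xlen_t>(Xo) * (oy + static_cast<R_xlen_t>(Yo) * oz));
      const R_xlen_t woff = static_cast<R_xlen_t>(C) * Cout * (i + static_cast<R_xlen_t>(s) * (j + static_cast<R_xlen_t>(s) * k));
      for (int co = 0; co < Cout; ++co) {
        const double gval = gyv[co];
        gbp[co] += gval;
        const double *wc = wp + woff + static_cast<R_xlen_t>(C) * co;
        double *gwc = gwp + woff + static_cast<R_xlen_t>(C) * co;
        for (int ci = 0; ci < C; ++ci) {
          gxp[xoff + ci] += wc[ci] * gval;
          gwc[ci] += xp[xoff + ci] * gval;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
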
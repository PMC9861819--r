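#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All volumes are column-major R arrays of dim (C, X, Y, Z): channel fastest.
// Dense conv weights come in as a (C*k^3) x Cout matrix whose row index is
// kx + k*ky + k^2*kz + k^3*ci, i.e. the flattening of an R array
// dim c(k, k, k, Cin, Cout). Depthwise weights are dim c(C, k, k, k).

static inline int conv_out(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill im2col columns for output slices [z0, z0+zn) of the output grid.
static void im2col_slab(const double* xp, int C, int X, int Y, int Z,
                        int k, int stride, int pad,
                        int OX, int OY, int z0, int zn, arma::mat& cols) {
  cols.zeros();
  const int k2 = k * k, k3 = k2 * k;
  for (int oz = 0; oz < zn; ++oz) {
    const int bz = (z0 + oz) * stride - pad;
    for (int oy = 0; oy < OY; ++oy) {
      const int by = oy * stride - pad;
      for (int ox = 0; ox < OX; ++ox) {
        const int bx = ox * stride - pad;
        double* col = cols.colptr((size_t)ox + (size_t)OX * (oy + (size_t)OY * oz));
        for (int kz = 0; kz < k; ++kz) {
          const int iz = bz + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = by + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = bx + kx;
              if (ix < 0 || ix >= X) continue;
              const double* xv = xp + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const int rb = kx + k * ky + k2 * kz;
              for (int ci = 0; ci < C; ++ci) col[rb + k3 * ci] = xv[ci];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of column gradients back onto the input grid (transpose of im2col).
static void col2im_slab(double* dxp, int C, int X, int Y, int Z,
                        int k, int stride, int pad,
                        int OX, int OY, int z0, int zn, const arma::mat& dcols) {
  const int k2 = k * k, k3 = k2 * k;
  for (int oz = 0; oz < zn; ++oz) {
    const int bz = (z0 + oz) * stride - pad;
    for (int oy = 0; oy < OY; ++oy) {
      const int by = oy * stride - pad;
      for (int ox = 0; ox < OX; ++ox) {
        const int bx = ox * stride - pad;
        const double* col = dcols.colptr((size_t)ox + (size_t)OX * (oy + (size_t)OY * oz));
        for (int kz = 0; kz < k; ++kz) {
          const int iz = bz + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = by + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = bx + kx;
              if (ix < 0 || ix >= X) continue;
              double* xv = dxp + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const int rb = kx + k * ky + k2 * kz;
              for (int ci = 0; ci < C; ++ci) xv[ci] += col[rb + k3 * ci];
            }
          }
        }
      }
    }
  }
}

static int slab_size(int R, int OX, int OY) {
  int slab = (int)(8e6 / ((double)R * OX * OY + 1.0));
  if (slab < 1) slab = 1;
  return slab;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericMatrix w, int k, int cout,
                            int stride, int pad) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = conv_out(X, k, stride, pad), OY = conv_out(Y, k, stride, pad),
            OZ = conv_out(Z, k, stride, pad);
  const int R = C * k * k * k;
  arma::mat W(w.begin(), R, cout, false);
  NumericVector out((size_t)cout * OX * OY * OZ);
  out.attr("dim") = IntegerVector::create(cout, OX, OY, OZ);
  const int slab = slab_size(R, OX, OY);
  arma::mat cols(R, (size_t)OX * OY * std::min(slab, OZ));
  for (int z0 = 0; z0 < OZ; z0 += slab) {
    const int zn = std::min(slab, OZ - z0);
    const size_t N = (size_t)OX * OY * zn;
    im2col_slab(x.begin(), C, X, Y, Z, k, stride, pad, OX, OY, z0, zn, cols);
    arma::mat Yv(out.begin() + (size_t)cout * OX * OY * z0, cout, N, false, true);
    Yv = W.t() * cols.cols(0, N - 1);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim,
                   NumericMatrix w, int k, int cout,
                   int stride, int pad, NumericVector dy) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = conv_out(X, k, stride, pad), OY = conv_out(Y, k, stride, pad),
            OZ = conv_out(Z, k, stride, pad);
  const int R = C * k * k * k;
  arma::mat W(w.begin(), R, cout, false);
  NumericMatrix dwr(R, cout);
  arma::mat dW(dwr.begin(), R, cout, false);
  NumericVector dx((size_t)C * X * Y * Z);
  dx.attr("dim") = xdim;
  const int slab = slab_size(R, OX, OY);
  arma::mat cols(R, (size_t)OX * OY * std::min(slab, OZ));
  for (int z0 = 0; z0 < OZ; z0 += slab) {
    const int zn = std::min(slab, OZ - z0);
    const size_t N = (size_t)OX * OY * zn;
    im2col_slab(x.begin(), C, X, Y, Z, k, stride, pad, OX, OY, z0, zn, cols);
    arma::mat dYv(dy.begin() + (size_t)cout * OX * OY * z0, cout, N, false, true);
    dW += cols.cols(0, N - 1) * dYv.t();
    arma::mat dcols = W * dYv;
    col2im_slab(dx.begin(), C, X, Y, Z, k, stride, pad, OX, OY, z0, zn, dcols);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwr);
}

// Depthwise 3D convolution, weights dim c(C, k, k, k).
// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fw(NumericVector x, IntegerVector xdim,
                              NumericVector w, int k, int stride, int pad) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = conv_out(X, k, stride, pad), OY = conv_out(Y, k, stride, pad),
            OZ = conv_out(Z, k, stride, pad);
  NumericVector out((size_t)C * OX * OY * OZ);
  out.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int oz = 0; oz < OZ; ++oz) {
    const int bz = oz * stride - pad;
    for (int oy = 0; oy < OY; ++oy) {
      const int by = oy * stride - pad;
      for (int ox = 0; ox < OX; ++ox) {
        const int bx = ox * stride - pad;
        double* yv = op + (size_t)C * (ox + (size_t)OX * (oy + (size_t)OY * oz));
        for (int kz = 0; kz < k; ++kz) {
          const int iz = bz + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = by + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = bx + kx;
              if (ix < 0 || ix >= X) continue;
              const double* xv = xp + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const double* wv = wp + (size_t)C * (kx + (size_t)k * (ky + (size_t)k * kz));
              for (int c = 0; c < C; ++c) yv[c] += wv[c] * xv[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv3d_bw(NumericVector x, IntegerVector xdim,
                     NumericVector w, int k, int stride, int pad,
                     NumericVector dy) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = conv_out(X, k, stride, pad), OY = conv_out(Y, k, stride, pad),
            OZ = conv_out(Z, k, stride, pad);
  NumericVector dx((size_t)C * X * Y * Z);
  dx.attr("dim") = xdim;
  NumericVector dw((size_t)C * k * k * k);
  dw.attr("dim") = IntegerVector::create(C, k, k, k);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int oz = 0; oz < OZ; ++oz) {
    const int bz = oz * stride - pad;
    for (int oy = 0; oy < OY; ++oy) {
      const int by = oy * stride - pad;
      for (int ox = 0; ox < OX; ++ox) {
        const int bx = ox * stride - pad;
        const double* gv = dyp + (size_t)C * (ox + (size_t)OX * (oy + (size_t)OY * oz));
        for (int kz = 0; kz < k; ++kz) {
          const int iz = bz + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = by + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = bx + kx;
              if (ix < 0 || ix >= X) continue;
              const size_t xoff = (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const size_t woff = (size_t)C * (kx + (size_t)k * (ky + (size_t)k * kz));
              for (int c = 0; c < C; ++c) {
                dxp[xoff + c] += wp[woff + c] * gv[c];
                dwp[woff + c] += xp[xoff + c] * gv[c];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Block mean/sum pooling by integer factor f on each spatial axis.
// [[Rcpp::export]]
NumericVector cpp_block_reduce(NumericVector x, IntegerVector xdim, int f, bool mean) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = X / f, OY = Y / f, OZ = Z / f;
  NumericVector out((size_t)C * OX * OY * OZ);
  out.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int z = 0; z < Z; ++z) {
    for (int y = 0; y < Y; ++y) {
      for (int xx = 0; xx < X; ++xx) {
        const double* xv = xp + (size_t)C * (xx + (size_t)X * (y + (size_t)Y * z));
        double* ov = op + (size_t)C * ((xx / f) + (size_t)OX * ((y / f) + (size_t)OY * (z / f)));
        for (int c = 0; c < C; ++c) ov[c] += xv[c];
      }
    }
  }
  if (mean) {
    const double inv = 1.0 / ((double)f * f * f);
    for (R_xlen_t i = 0; i < out.size(); ++i) op[i] *= inv;
  }
  return out;
}

// Nearest-neighbour style block expansion by factor f, multiplied by `scale`.
// [[Rcpp::export]]
NumericVector cpp_block_expand(NumericVector x, IntegerVector xdim, int f, double scale) {
  const int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3];
  const int OX = X * f, OY = Y * f, OZ = Z * f;
  NumericVector out((size_t)C * OX * OY * OZ);
  out.attr("dim") = IntegerVector::create(C, OX, OY, OZ);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int z = 0; z < OZ; ++z) {
    for (int y = 0; y < OY; ++y) {
      for (int xx = 0; xx < OX; ++xx) {
        const double* xv = xp + (size_t)C * ((xx / f) + (size_t)X * ((y / f) + (size_t)Y * (z / f)));
        double* ov = op + (size_t)C * (xx + (size_t)OX * (y + (size_t)OY * z));
        for (int c = 0; c < C; ++c) ov[c] = scale * xv[c];
      }
    }
  }
  return out;
}

// Surface voxels of a binary mask under 6-connectivity; voxels on the image
// border count as surface (outside the volume is background).
// [[Rcpp::export]]
IntegerMatrix cpp_surface_voxels(LogicalVector mask, IntegerVector mdim) {
  const int X = mdim[0], Y = mdim[1], Z = mdim[2];
  const int* mp = mask.begin();
  std::vector<int> xs, ys, zs;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const size_t i = (size_t)x + (size_t)X * (y + (size_t)Y * z);
        if (!mp[i]) continue;
        bool surf = false;
        if (x == 0 || !mp[i - 1]) surf = true;
        else if (x == X - 1 || !mp[i + 1]) surf = true;
        else if (y == 0 || !mp[i - X]) surf = true;
        else if (y == Y - 1 || !mp[i + X]) surf = true;
        else if (z == 0 || !mp[i - (size_t)X * Y]) surf = true;
        else if (z == Z - 1 || !mp[i + (size_t)X * Y]) surf = true;
        if (surf) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// For each row of A, Euclidean distance (scaled by voxel spacing) to the
// nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(IntegerMatrix A, IntegerMatrix B, NumericVector spacing) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0) * sx, dy = ay - B(j, 1) * sy, dz = az - B(j, 2) * sz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
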
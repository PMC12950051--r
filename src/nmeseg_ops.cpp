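// Low-level volumetric kernels: im2col/GEMM 3D convolution with exact
// backward passes, max-pooling, trilinear resampling under a rigid map,
// separable Gaussian smoothing, 6-connected labelling and box morphology.
//
// Feature tensors are flat numeric vectors in column-major layout
// (nx, ny, nz, B, C): index = ix + nx*(iy + ny*(iz + nz*(b + B*c))).
// Plain volumes are (nx, ny, nz).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t vidx5(int ix, int iy, int iz, int b, int c,
                             int nx, int ny, int nz, int B) {
  return (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * (iz + (R_xlen_t)nz * (b + (R_xlen_t)B * c)));
}

// Fill the (N x K) patch matrix for one batch element over slices [z0, z1).
// K = Cin * k^3, row n enumerates (ix, iy, iz) within the slab.
static void im2col_slab(const double* x, int nx, int ny, int nz, int B, int Cin,
                        int b, int z0, int z1, int k, arma::mat& colmat) {
  const int r = k / 2;
  const int slab = z1 - z0;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + vidx5(0, 0, 0, b, ci, nx, ny, nz, B);
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const int kk = ((ci * k + dz) * k + dy) * k + dx;
          double* col = colmat.colptr(kk);
          for (int iz = z0; iz < z1; ++iz) {
            const int sz = iz + dz - r;
            double* dst = col + (R_xlen_t)(iz - z0) * plane;
            if (sz < 0 || sz >= nz) {
              std::memset(dst, 0, sizeof(double) * plane);
              continue;
            }
            for (int iy = 0; iy < ny; ++iy) {
              const int sy = iy + dy - r;
              double* drow = dst + (R_xlen_t)iy * nx;
              if (sy < 0 || sy >= ny) {
                std::memset(drow, 0, sizeof(double) * nx);
                continue;
              }
              const double* srow = xc + (R_xlen_t)sz * plane + (R_xlen_t)sy * nx;
              const int sx0 = dx - r;        // source x of output ix = 0
              int lo = std::max(0, -sx0);
              int hi = std::min(nx, nx - sx0);
              if (lo > 0) std::memset(drow, 0, sizeof(double) * lo);
              if (hi < nx) std::memset(drow + hi, 0, sizeof(double) * (nx - hi));
              if (hi > lo)
                std::memcpy(drow + lo, srow + lo + sx0, sizeof(double) * (hi - lo));
            }
          }
          (void)slab;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                            const arma::mat& w, const arma::vec& bias, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3], Cin = dims[4];
  const int Cout = w.n_rows;
  const int K = Cin * k * k * k;
  if ((int)w.n_cols != K) stop("weight/kernel size mismatch");
  NumericVector out((R_xlen_t)nx * ny * nz * B * Cout);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const int chunk = std::min<R_xlen_t>(
      nz, std::max<R_xlen_t>(1, 4000000 / std::max<R_xlen_t>(1, plane * K)));
  arma::mat wt = w.t();                       // K x Cout
  arma::mat colmat(plane * chunk, K);         // reused across chunks/batch
  for (int b = 0; b < B; ++b) {
    for (int z0 = 0; z0 < nz; z0 += chunk) {
      const int z1 = std::min(nz, z0 + chunk);
      const R_xlen_t N = plane * (z1 - z0);
      arma::mat colview(colmat.memptr(), N, K, false, true);
      im2col_slab(xp, nx, ny, nz, B, Cin, b, z0, z1, k, colview);
      arma::mat y = colview * wt;             // N x Cout
      for (int co = 0; co < Cout; ++co) {
        double* dst = op + vidx5(0, 0, z0, b, co, nx, ny, nz, B);
        const double* src = y.colptr(co);
        const double bb = bias[co];
        for (R_xlen_t i = 0; i < N; ++i) dst[i] = src[i] + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims, const arma::mat& w,
                   NumericVector gy, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3], Cin = dims[4];
  const int Cout = w.n_rows;
  const int K = Cin * k * k * k;
  const int r = k / 2;
  NumericVector gx((R_xlen_t)nx * ny * nz * B * Cin);
  arma::mat gw(Cout, K, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const int chunk = std::min<R_xlen_t>(
      nz, std::max<R_xlen_t>(1, 4000000 / std::max<R_xlen_t>(1, plane * K)));
  arma::mat colmat(plane * chunk, K);
  arma::mat colg_buf(plane * chunk, K);
  arma::mat Gbuf(plane * chunk, Cout);
  for (int b = 0; b < B; ++b) {
    for (int z0 = 0; z0 < nz; z0 += chunk) {
      const int z1 = std::min(nz, z0 + chunk);
      const R_xlen_t N = plane * (z1 - z0);
      arma::mat colview(colmat.memptr(), N, K, false, true);
      im2col_slab(xp, nx, ny, nz, B, Cin, b, z0, z1, k, colview);
      arma::mat G(Gbuf.memptr(), N, Cout, false, true);
      for (int co = 0; co < Cout; ++co) {
        const double* src = gp + vidx5(0, 0, z0, b, co, nx, ny, nz, B);
        std::memcpy(G.colptr(co), src, sizeof(double) * N);
      }
      gw += G.t() * colview;
      gb += arma::sum(G, 0).t();
      arma::mat colg(colg_buf.memptr(), N, K, false, true);
      colg = G * w;                           // N x K
      // scatter-add back into gx (reverse of im2col)
      for (int ci = 0; ci < Cin; ++ci) {
        double* gxc = gxp + vidx5(0, 0, 0, b, ci, nx, ny, nz, B);
        for (int dz = 0; dz < k; ++dz) {
          for (int dy = 0; dy < k; ++dy) {
            for (int dx = 0; dx < k; ++dx) {
              const int kk = ((ci * k + dz) * k + dy) * k + dx;
              const double* col = colg.colptr(kk);
              for (int iz = z0; iz < z1; ++iz) {
                const int sz = iz + dz - r;
                if (sz < 0 || sz >= nz) continue;
                const double* srow0 = col + (R_xlen_t)(iz - z0) * plane;
                for (int iy = 0; iy < ny; ++iy) {
                  const int sy = iy + dy - r;
                  if (sy < 0 || sy >= ny) continue;
                  const double* srow = srow0 + (R_xlen_t)iy * nx;
                  double* drow = gxc + (R_xlen_t)sz * plane + (R_xlen_t)sy * nx;
                  const int sx0 = dx - r;
                  const int lo = std::max(0, -sx0);
                  const int hi = std::min(nx, nx - sx0);
                  for (int ix = lo; ix < hi; ++ix) drow[ix + sx0] += srow[ix];
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector dims, IntegerVector f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], B = dims[3], C = dims[4];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  const R_xlen_t n_out = (R_xlen_t)ox * oy * oz * B * C;
  NumericVector y(n_out);
  NumericVector idx(n_out);      // 1-based linear index into x (double: may exceed int)
  double* yp = REAL(y);
  double* ip = REAL(idx);
  const double* xp = REAL(x);
  R_xlen_t n = 0;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b)
      for (int kz = 0; kz < oz; ++kz)
        for (int ky = 0; ky < oy; ++ky)
          for (int kx = 0; kx < ox; ++kx) {
            double best = -HUGE_VAL; R_xlen_t bi = 0;
            for (int dz = 0; dz < fz; ++dz)
              for (int dy = 0; dy < fy; ++dy)
                for (int dx = 0; dx < fx; ++dx) {
                  R_xlen_t ii = vidx5(kx * fx + dx, ky * fy + dy, kz * fz + dz, b, c, nx, ny, nz, B);
                  if (xp[ii] > best) { best = xp[ii]; bi = ii; }
                }
            R_xlen_t oi = vidx5(kx, ky, kz, b, c, ox, oy, oz, B);
            yp[oi] = best; ip[oi] = (double)(bi + 1);
            ++n;
          }
  (void)n;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(NumericVector idx, NumericVector gy, double n_x) {
  NumericVector gx((R_xlen_t)n_x);
  double* gp = REAL(gx);
  const double* ip = REAL(idx);
  const double* gyp = REAL(gy);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gp[(R_xlen_t)ip[i] - 1] += gyp[i];
  return gx;
}

// Resample `vol` onto its own grid under the rigid map applied to world
// coordinates: q = R * (p - center) + center + t, trilinear interpolation,
// zero outside the field of view. Also returns an in-field indicator.
// [[Rcpp::export]]
List cpp_resample_rigid(NumericVector vol, IntegerVector dims, NumericVector spacing,
                        NumericVector rotmat, NumericVector trans, NumericVector center) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  LogicalVector inside((R_xlen_t)nx * ny * nz);
  const double* vp = REAL(vol);
  double* op = REAL(out);
  int* insp = LOGICAL(inside);
  const double* Rm = REAL(rotmat);   // column-major 3x3
  R_xlen_t n = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double pz = iz * sz - center[2];
    for (int iy = 0; iy < ny; ++iy) {
      const double py = iy * sy - center[1];
      for (int ix = 0; ix < nx; ++ix, ++n) {
        const double px = ix * sx - center[0];
        const double qx = Rm[0] * px + Rm[3] * py + Rm[6] * pz + center[0] + trans[0];
        const double qy = Rm[1] * px + Rm[4] * py + Rm[7] * pz + center[1] + trans[1];
        const double qz = Rm[2] * px + Rm[5] * py + Rm[8] * pz + center[2] + trans[2];
        const double gx = qx / sx, gy = qy / sy, gz = qz / sz;
        const int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy), z0 = (int)std::floor(gz);
        if (x0 < 0 || x0 + 1 >= nx || y0 < 0 || y0 + 1 >= ny || z0 < 0 || z0 + 1 >= nz) {
          op[n] = 0.0; insp[n] = FALSE; continue;
        }
        const double wx = gx - x0, wy = gy - y0, wz = gz - z0;
        const R_xlen_t i000 = (R_xlen_t)x0 + nx * ((R_xlen_t)y0 + (R_xlen_t)ny * z0);
        const R_xlen_t dxs = 1, dys = nx, dzs = (R_xlen_t)nx * ny;
        const double c00 = vp[i000] * (1 - wx) + vp[i000 + dxs] * wx;
        const double c10 = vp[i000 + dys] * (1 - wx) + vp[i000 + dys + dxs] * wx;
        const double c01 = vp[i000 + dzs] * (1 - wx) + vp[i000 + dzs + dxs] * wx;
        const double c11 = vp[i000 + dzs + dys] * (1 - wx) + vp[i000 + dzs + dys + dxs] * wx;
        const double c0 = c00 * (1 - wy) + c10 * wy;
        const double c1 = c01 * (1 - wy) + c11 * wy;
        op[n] = c0 * (1 - wz) + c1 * wz;
        insp[n] = TRUE;
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

static void blur_axis(std::vector<double>& v, int nx, int ny, int nz,
                      double sigma, int axis) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += kern[i + r]; }
  for (double& k : kern) k /= s;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int j2 = 0; j2 < n[a2]; ++j2)
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      const R_xlen_t base = (R_xlen_t)j1 * stride[a1] + (R_xlen_t)j2 * stride[a2];
      for (int i = 0; i < len; ++i) line[i] = v[base + (R_xlen_t)i * st];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int dk = -r; dk <= r; ++dk) {
          int s2 = i + dk;
          if (s2 < 0) s2 = -s2 - 1;            // reflect
          if (s2 >= len) s2 = 2 * len - s2 - 1;
          acc += kern[dk + r] * line[s2];
        }
        v[base + (R_xlen_t)i * st] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector x, IntegerVector dims, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(REAL(x), REAL(x) + (R_xlen_t)nx * ny * nz);
  blur_axis(v, nx, ny, nz, sigma[0], 0);
  blur_axis(v, nx, ny, nz, sigma[1], 1);
  blur_axis(v, nx, ny, nz, sigma[2], 2);
  return NumericVector(v.begin(), v.end());
}

// 6-connected component labelling of a binary volume.
// [[Rcpp::export]]
List cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  const int* mp = LOGICAL(mask);
  int* lp = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  const R_xlen_t dxs = 1, dys = nx, dzs = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mp[i] || lp[i]) continue;
    ++ncomp;
    stack.push_back(i);
    lp[i] = ncomp;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int iz = (int)(cur / dzs);
      const int iy = (int)((cur - iz * dzs) / dys);
      const int ix = (int)(cur - iz * dzs - (R_xlen_t)iy * dys);
      const R_xlen_t nb[6] = {cur - dxs, cur + dxs, cur - dys, cur + dys, cur - dzs, cur + dzs};
      const bool ok[6] = {ix > 0, ix < nx - 1, iy > 0, iy < ny - 1, iz > 0, iz < nz - 1};
      for (int d = 0; d < 6; ++d)
        if (ok[d] && mp[nb[d]] && !lp[nb[d]]) { lp[nb[d]] = ncomp; stack.push_back(nb[d]); }
    }
  }
  return List::create(_["labels"] = lab, _["n"] = ncomp);
}

static void axis_minmax(std::vector<double>& v, int nx, int ny, int nz,
                        int r, int axis, bool do_max) {
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> line(len);
  for (int j2 = 0; j2 < n[a2]; ++j2)
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      const R_xlen_t base = (R_xlen_t)j1 * stride[a1] + (R_xlen_t)j2 * stride[a2];
      for (int i = 0; i < len; ++i) line[i] = v[base + (R_xlen_t)i * st];
      for (int i = 0; i < len; ++i) {
        double acc = line[i];
        for (int dk = -r; dk <= r; ++dk) {
          const int s2 = i + dk;
          if (s2 < 0 || s2 >= len) continue;
          if (do_max) acc = std::max(acc, line[s2]); else acc = std::min(acc, line[s2]);
        }
        v[base + (R_xlen_t)i * st] = acc;
      }
    }
}

// Box dilation (do_max) or erosion of a binary volume, radius r per axis.
// [[Rcpp::export]]
LogicalVector cpp_box_morph(LogicalVector mask, IntegerVector dims, int r, bool do_max) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> v(n);
  const int* mp = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = mp[i] ? 1.0 : 0.0;
  axis_minmax(v, nx, ny, nz, r, 0, do_max);
  axis_minmax(v, nx, ny, nz, r, 1, do_max);
  axis_minmax(v, nx, ny, nz, r, 2, do_max);
  LogicalVector out(n);
  int* op = LOGICAL(out);
  for (R_xlen_t i = 0; i < n; ++i) op[i] = v[i] > 0.5;
  return out;
}

// Count exposed voxel faces of a binary mask (digital surface area in faces).
// [[Rcpp::export]]
double cpp_surface_faces(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* mp = LOGICAL(mask);
  const R_xlen_t dys = nx, dzs = (R_xlen_t)nx * ny;
  double faces = 0;
  R_xlen_t i = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++i) {
        if (!mp[i]) continue;
        if (ix == 0 || !mp[i - 1]) ++faces;
        if (ix == nx - 1 || !mp[i + 1]) ++faces;
        if (iy == 0 || !mp[i - dys]) ++faces;
        if (iy == ny - 1 || !mp[i + dys]) ++faces;
        if (iz == 0 || !mp[i - dzs]) ++faces;
        if (iz == nz - 1 || !mp[i + dzs]) ++faces;
      }
  return faces;
}
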
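// Numerical kernels: convolution (im2col + GEMM), 2x2 transposed convolution,
// max pooling, ROI align, bilinear resampling, affine warps, Hausdorff
// distance, CRC32. Array layout follows R column-major conventions:
// feature maps are (H, W, C, N), kernels (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int dim4(const IntegerVector& d, int i) {
  return i < d.size() ? d[i] : 1;
}

// im2col for one sample. x points at (H,W,C) block. col is K x P with
// K = kh*kw*C, P = Ho*Wo; k decomposes as ki + kh*(kj + kw*c), p as ho + Ho*wo.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int krow = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          double* dst = col.colptr(0) + krow; // stride K between columns
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(krow, ho + (size_t)Ho * wo) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            col(krow, ho + (size_t)Ho * wo) =
              (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im_add(double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, const arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int krow = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H)
              xcw[hi] += col(krow, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, P = Ho * Wo;
  NumericVector y(Ho * Wo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat out(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    out = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, P = Ho * Wo;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat gyn(const_cast<double*>(gy.begin()) + (size_t)P * Cout * n,
                  P, Cout, false, true);
    gWm += col * gyn;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gyn.col(co));
    arma::mat gcol = Wm * gyn.t();
    col2im_add(gx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride,
               pad, Ho, Wo, gcol);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2x2, stride 2 (non-overlapping scatter).
// [[Rcpp::export]]
NumericVector cpp_convT2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)Ho * Wo * co;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] = b[co];
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xn + (size_t)H * W * ci;
        const double* wk = w.begin() + 4 * (ci + C * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            double v = xc[i + (size_t)H * j];
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                yc[(2 * i + di) + (size_t)Ho * (2 * j + dj)] +=
                  v * wk[di + 2 * dj];
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convT2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* gxn = gx.begin() + (size_t)H * W * C * n;
    const double* gyn = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gyc = gyn + (size_t)Ho * Wo * co;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) gb[co] += gyc[i];
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = xn + (size_t)H * W * ci;
        double* gxc = gxn + (size_t)H * W * ci;
        const double* wk = w.begin() + 4 * (ci + C * co);
        double* gwk = gw.begin() + 4 * (ci + C * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            double acc = 0.0;
            double v = xc[i + (size_t)H * j];
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                double g = gyc[(2 * i + di) + (size_t)Ho * (2 * j + dj)];
                acc += g * wk[di + 2 * dj];
                gwk[di + 2 * dj] += g * v;
              }
            gxc[i + (size_t)H * j] += acc;
          }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size()); arg.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + C * n);
      int* ac = arg.begin() + (size_t)Ho * Wo * (c + C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bidx = hi + H * wi; }
            }
          }
          yc[ho + (size_t)Ho * wo] = (bidx < 0) ? 0.0 : best;
          ac[ho + (size_t)Ho * wo] = bidx;
        }
    }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector arg,
                              IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = dim4(xdim, 3);
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gyc = gy.begin() + (size_t)Ho * Wo * (c + C * n);
      const int* ac = arg.begin() + (size_t)Ho * Wo * (c + C * n);
      double* gxc = gx.begin() + (size_t)H * W * (c + C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        if (ac[i] >= 0) gxc[ac[i]] += gyc[i];
    }
  return gx;
}

// Bilinear interpolation helper at continuous index coords (iy, ix),
// border-replicating clamp.
static inline double bilin(const double* m, int H, int W, double iy, double ix) {
  if (iy < 0) iy = 0; if (iy > H - 1) iy = H - 1;
  if (ix < 0) ix = 0; if (ix > W - 1) ix = W - 1;
  int y0 = (int)std::floor(iy), x0 = (int)std::floor(ix);
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double fy = iy - y0, fx = ix - x0;
  double a = m[y0 + (size_t)H * x0], b = m[y1 + (size_t)H * x0];
  double c = m[y0 + (size_t)H * x1], d = m[y1 + (size_t)H * x1];
  return a * (1 - fy) * (1 - fx) + b * fy * (1 - fx) +
         c * (1 - fy) * fx + d * fy * fx;
}

// Resize a (H,W) matrix with half-pixel-center alignment (the OpenCV
// convention): src_i = (dst_i + 0.5) * H/Ho - 0.5.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix src, int Ho, int Wo) {
  int H = src.nrow(), W = src.ncol();
  NumericMatrix out(Ho, Wo);
  double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int j = 0; j < Wo; ++j) {
    double ix = (j + 0.5) * sx - 0.5;
    for (int i = 0; i < Ho; ++i) {
      double iy = (i + 0.5) * sy - 0.5;
      out(i, j) = bilin(src.begin(), H, W, iy, ix);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix src, int Ho, int Wo) {
  int H = src.nrow(), W = src.ncol();
  NumericMatrix out(Ho, Wo);
  double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int j = 0; j < Wo; ++j) {
    int x = std::min(W - 1, std::max(0, (int)std::floor((j + 0.5) * sx)));
    for (int i = 0; i < Ho; ++i) {
      int y = std::min(H - 1, std::max(0, (int)std::floor((i + 0.5) * sy)));
      out(i, j) = src(y, x);
    }
  }
  return out;
}

// Affine warp: dst(r,c) = src(M %*% (c, r, 1)) with M a 2x3 matrix giving
// (src_x, src_y); zero fill outside, bilinear sampling in index coords.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix src, NumericMatrix M,
                              int Ho, int Wo) {
  int H = src.nrow(), W = src.ncol();
  NumericMatrix out(Ho, Wo);
  for (int c = 0; c < Wo; ++c)
    for (int r = 0; r < Ho; ++r) {
      double sx = M(0, 0) * c + M(0, 1) * r + M(0, 2);
      double sy = M(1, 0) * c + M(1, 1) * r + M(1, 2);
      if (sx < -0.5 || sx > W - 0.5 || sy < -0.5 || sy > H - 0.5) {
        out(r, c) = 0.0;
      } else {
        out(r, c) = bilin(src.begin(), H, W, sy, sx);
      }
    }
  return out;
}

// ROI align on one feature level. feat (H,W,C); boxes n x 4 (x1,y1,x2,y2) in
// feature-map units, half-open continuous coords where pixel i spans [i,i+1).
// Output (d,d,C,n). `samples` sub-points per bin axis (standard: 2).
// [[Rcpp::export]]
NumericVector cpp_roialign_fwd(NumericVector feat, NumericMatrix boxes,
                               int d, int samples) {
  IntegerVector fd = feat.attr("dim");
  int H = fd[0], W = fd[1], C = fd[2];
  int n = boxes.nrow();
  NumericVector out((size_t)d * d * C * n);
  out.attr("dim") = IntegerVector::create(d, d, C, n);
  for (int b = 0; b < n; ++b) {
    double x1 = boxes(b, 0), y1 = boxes(b, 1), x2 = boxes(b, 2), y2 = boxes(b, 3);
    double bw = std::max(x2 - x1, 1e-6), bh = std::max(y2 - y1, 1e-6);
    double binw = bw / d, binh = bh / d;
    for (int c = 0; c < C; ++c) {
      const double* fc = feat.begin() + (size_t)H * W * c;
      double* oc = out.begin() + (size_t)d * d * (c + (size_t)C * b);
      for (int pw = 0; pw < d; ++pw)
        for (int ph = 0; ph < d; ++ph) {
          double acc = 0.0;
          for (int sj = 0; sj < samples; ++sj) {
            double x = x1 + (pw + (sj + 0.5) / samples) * binw;
            for (int si = 0; si < samples; ++si) {
              double y = y1 + (ph + (si + 0.5) / samples) * binh;
              acc += bilin(fc, H, W, y - 0.5, x - 0.5);
            }
          }
          oc[ph + (size_t)d * pw] = acc / (samples * samples);
        }
    }
  }
  return out;
}

static inline void bilin_scatter(double* m, int H, int W, double iy, double ix,
                                 double g) {
  if (iy < 0) iy = 0; if (iy > H - 1) iy = H - 1;
  if (ix < 0) ix = 0; if (ix > W - 1) ix = W - 1;
  int y0 = (int)std::floor(iy), x0 = (int)std::floor(ix);
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double fy = iy - y0, fx = ix - x0;
  m[y0 + (size_t)H * x0] += g * (1 - fy) * (1 - fx);
  m[y1 + (size_t)H * x0] += g * fy * (1 - fx);
  m[y0 + (size_t)H * x1] += g * (1 - fy) * fx;
  m[y1 + (size_t)H * x1] += g * fy * fx;
}

// [[Rcpp::export]]
NumericVector cpp_roialign_bwd(NumericVector gout, NumericMatrix boxes,
                               IntegerVector featdim, int d, int samples) {
  int H = featdim[0], W = featdim[1], C = featdim[2];
  int n = boxes.nrow();
  NumericVector gfeat((size_t)H * W * C);
  gfeat.attr("dim") = featdim;
  for (int b = 0; b < n; ++b) {
    double x1 = boxes(b, 0), y1 = boxes(b, 1), x2 = boxes(b, 2), y2 = boxes(b, 3);
    double bw = std::max(x2 - x1, 1e-6), bh = std::max(y2 - y1, 1e-6);
    double binw = bw / d, binh = bh / d;
    for (int c = 0; c < C; ++c) {
      double* gc = gfeat.begin() + (size_t)H * W * c;
      const double* oc = gout.begin() + (size_t)d * d * (c + (size_t)C * b);
      for (int pw = 0; pw < d; ++pw)
        for (int ph = 0; ph < d; ++ph) {
          double g = oc[ph + (size_t)d * pw] / (samples * samples);
          for (int sj = 0; sj < samples; ++sj) {
            double x = x1 + (pw + (sj + 0.5) / samples) * binw;
            for (int si = 0; si < samples; ++si) {
              double y = y1 + (ph + (si + 0.5) / samples) * binh;
              bilin_scatter(gc, H, W, y - 0.5, x - 0.5, g);
            }
          }
        }
    }
  }
  return gfeat;
}

// Symmetric Hausdorff distance between two point sets (n x 2 each).
// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  double hab = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = INFINITY;
    for (int j = 0; j < m; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    if (best > hab) hab = best;
  }
  double hba = 0.0;
  for (int j = 0; j < m; ++j) {
    double best = INFINITY;
    for (int i = 0; i < n; ++i) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    if (best > hba) hba = best;
  }
  return std::sqrt(std::max(hab, hba));
}

// [[Rcpp::export]]
IntegerVector cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  IntegerVector out(4);
  out[0] = (crc >> 24) & 0xFF; out[1] = (crc >> 16) & 0xFF;
  out[2] = (crc >> 8) & 0xFF; out[3] = crc & 0xFF;
  return out;
}

// Zhang-Suen thinning to convergence. m is 0/1 integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix m) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix x = clone(m);
  auto at = [&](int r, int c) -> int {
    return (r >= 0 && r < H && c >= 0 && c < W) ? x(r, c) : 0;
  };
  std::vector<std::pair<int,int>> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (!x(r, c)) continue;
          // neighbours P2..P9 clockwise from north (row - 1)
          int p[8] = { at(r-1,c), at(r-1,c+1), at(r,c+1), at(r+1,c+1),
                       at(r+1,c), at(r+1,c-1), at(r,c-1), at(r-1,c-1) };
          int B = 0; for (int i = 0; i < 8; ++i) B += p[i];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int i = 0; i < 8; ++i) A += (p[i] == 0 && p[(i+1)%8] == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0]*p[2]*p[4] != 0 || p[2]*p[4]*p[6] != 0) continue;
          } else {
            if (p[0]*p[2]*p[6] != 0 || p[0]*p[4]*p[6] != 0) continue;
          }
          del.push_back({r, c});
        }
      if (!del.empty()) changed = true;
      for (auto& rc : del) x(rc.first, rc.second) = 0;
    }
  }
  // remove remaining 2x2 blocks where deletion keeps connectivity (A == 1)
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c + 1 < W && !changed; ++c)
      for (int r = 0; r + 1 < H && !changed; ++r) {
        if (!(x(r,c) && x(r+1,c) && x(r,c+1) && x(r+1,c+1))) continue;
        int rr[4] = {r, r, r+1, r+1}, cc[4] = {c, c+1, c, c+1};
        for (int k = 0; k < 4; ++k) {
          x(rr[k], cc[k]) = 0;
          int p[8] = { at(rr[k]-1,cc[k]), at(rr[k]-1,cc[k]+1), at(rr[k],cc[k]+1),
                       at(rr[k]+1,cc[k]+1), at(rr[k]+1,cc[k]), at(rr[k]+1,cc[k]-1),
                       at(rr[k],cc[k]-1), at(rr[k]-1,cc[k]-1) };
          int A = 0, B = 0;
          for (int i = 0; i < 8; ++i) { B += p[i]; A += (p[i]==0 && p[(i+1)%8]==1); }
          if (A == 1 && B >= 2) { changed = true; break; }
          x(rr[k], cc[k]) = 1;
        }
      }
  }
  return x;
}

// For each query point, min distance to a set of (continuous) points.
// [[Rcpp::export]]
NumericVector cpp_min_dist_points(NumericVector qx, NumericVector qy,
                                  NumericVector px, NumericVector py) {
  int n = qx.size(), m = px.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = INFINITY;
    for (int j = 0; j < m; ++j) {
      double dx = qx[i] - px[j], dy = qy[i] - py[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Greedy IoU NMS; returns 1-based indices of kept boxes in score order.
// [[Rcpp::export]]
IntegerVector cpp_nms(NumericMatrix boxes, NumericVector scores,
                      double thresh, int maxKeep) {
  int n = boxes.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double* sc = scores.begin();
  std::stable_sort(ord.begin(), ord.end(),
                   [sc](int a, int b) { return sc[a] > sc[b]; });
  // copy into sorted flat arrays for sequential access
  std::vector<double> x1(n), y1(n), x2(n), y2(n), area(n);
  const double* B = boxes.begin();
  for (int k = 0; k < n; ++k) {
    int i = ord[k];
    x1[k] = B[i]; y1[k] = B[i + n]; x2[k] = B[i + 2 * n]; y2[k] = B[i + 3 * n];
    area[k] = (x2[k] - x1[k]) * (y2[k] - y1[k]);
  }
  std::vector<char> dead(n, 0);
  std::vector<int> keep;
  for (int k = 0; k < n && (int)keep.size() < maxKeep; ++k) {
    if (dead[k]) continue;
    keep.push_back(ord[k] + 1);
    double ax1 = x1[k], ay1 = y1[k], ax2 = x2[k], ay2 = y2[k], aa = area[k];
    for (int j = k + 1; j < n; ++j) {
      if (dead[j]) continue;
      double iw = std::min(ax2, x2[j]) - std::max(ax1, x1[j]);
      if (iw <= 0) continue;
      double ih = std::min(ay2, y2[j]) - std::max(ay1, y1[j]);
      if (ih <= 0) continue;
      double inter = iw * ih;
      if (inter > thresh * (aa + area[j] - inter)) dead[j] = 1;
    }
  }
  return wrap(keep);
}

// Fused batch norm over (H, W, N) per channel (dim 3), batch statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  size_t plane = (size_t)H * W;
  NumericVector y(x.size()); y.attr("dim") = xd;
  NumericVector mu(C), inv(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) s += xc[i];
    }
    double m = s / (plane * N);
    double v = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { double d = xc[i] - m; v += d * d; }
    }
    v /= plane * N;
    double iv = 1.0 / std::sqrt(v + eps);
    mu[c] = m; inv[c] = iv;
    double g = gamma[c] * iv, b = beta[c] - gamma[c] * iv * m;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yc[i] = g * xc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
                NumericVector mu, NumericVector inv) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xh = (xc[i] - mu[c]) * inv[c];
        sg += gc[i];
        sgx += gc[i] * xh;
      }
    }
    dbeta[c] = sg; dgamma[c] = sgx;
    double k = gamma[c] * inv[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      double* gxc = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xh = (xc[i] - mu[c]) * inv[c];
        gxc[i] = k * (gc[i] - sg / m - xh * sgx / m);
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// conv forward that also returns the im2col matrices for backward reuse
// [[Rcpp::export]]
List cpp_conv2d_fwd_col(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = dim4(xd, 3);
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, P = Ho * Wo;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  NumericVector cols((size_t)K * P * N);
  cols.attr("dim") = IntegerVector::create(K, P, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat col(cols.begin() + (size_t)K * P * n, K, P, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat out(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    out = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
  }
  return List::create(_["y"] = y, _["col"] = cols);
}

// conv backward from cached im2col matrices
// [[Rcpp::export]]
List cpp_conv2d_bwd_col(NumericVector cols, NumericVector w, NumericVector gy,
                        IntegerVector xdim, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = dim4(xdim, 3);
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, P = Ho * Wo;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat col(const_cast<double*>(cols.begin()) + (size_t)K * P * n,
                  K, P, false, true);
    arma::mat gyn(const_cast<double*>(gy.begin()) + (size_t)P * Cout * n,
                  P, Cout, false, true);
    gWm += col * gyn;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gyn.col(co));
    arma::mat gcol = Wm * gyn.t();
    col2im_add(gx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride,
               pad, Ho, Wo, gcol);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Ridge (crest) extraction from a scalar field: keep pixels at or above
// `thresh` that are not dominated by either neighbour along the quantized
// gradient direction (non-maximum suppression, Canny style).
// [[Rcpp::export]]
IntegerMatrix cpp_field_ridge(NumericMatrix f, double thresh) {
  int H = f.nrow(), W = f.ncol();
  IntegerMatrix out(H, W);
  auto at = [&](int r, int c) -> double {
    if (r < 0) r = 0; if (r >= H) r = H - 1;
    if (c < 0) c = 0; if (c >= W) c = W - 1;
    return f(r, c);
  };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = f(r, c);
      if (v < thresh) continue;
      double gx = (at(r, c + 1) - at(r, c - 1)) / 2.0;
      double gy = (at(r + 1, c) - at(r - 1, c)) / 2.0;
      int dr, dc;
      if (std::abs(gx) > 2.414 * std::abs(gy)) { dr = 0; dc = 1; }
      else if (std::abs(gy) > 2.414 * std::abs(gx)) { dr = 1; dc = 0; }
      else if ((gx > 0) == (gy > 0)) { dr = 1; dc = 1; }
      else { dr = 1; dc = -1; }
      if (v >= at(r + dr, c + dc) && v >= at(r - dr, c - dc))
        out(r, c) = 1;
    }
  return out;
}
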
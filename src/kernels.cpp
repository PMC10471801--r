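#include <Rcpp.h>
#include <queue>
#include <cstring>
using namespace Rcpp;

// 8-connected component labelling of a binary matrix (H x W, column-major).
// Labels are assigned in the order of each component's first pixel in a
// row-major scan (row 1 left to right, then row 2, ...).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (x(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          int pr = q.front().first, pc = q.front().second;
          q.pop();
          for (int dr = -1; dr <= 1; ++dr) {
            for (int dc = -1; dc <= 1; ++dc) {
              int nr = pr + dr, nc = pc + dc;
              if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
              if (x(nr, nc) != 0 && lab(nr, nc) == 0) {
                lab(nr, nc) = next;
                q.push(std::make_pair(nr, nc));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// 4-connected labelling (used for background pockets / holes)
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const IntegerMatrix& x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (x(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          int pr = q.front().first, pc = q.front().second;
          q.pop();
          for (int k = 0; k < 4; ++k) {
            int nr = pr + dr[k], nc = pc + dc[k];
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (x(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              q.push(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Tensors are stored as numeric vectors with layout (C, H, W, N),
// C fastest (index = c + C*(h + H*(w + W*n))).

static inline long idx4(int c, int h, int w, int n, int C, int H, int W) {
  return c + (long)C * (h + (long)H * (w + (long)W * n));
}

// im2col for grouped=1 convolution: output K x L, K = C*KH*KW,
// L = OH*OW*N with column index oy + OH*(ox + OW*n); row index
// c + C*(ky + KH*kx). Zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int C, int H, int W, int N,
                         int KH, int KW, int SH, int SW, int PH, int PW,
                         int DH, int DW) {
  const int OH = (H + 2 * PH - DH * (KH - 1) - 1) / SH + 1;
  const int OW = (W + 2 * PW - DW * (KW - 1) - 1) / SW + 1;
  const long K = (long)C * KH * KW, L = (long)OH * OW * N;
  NumericMatrix cols(K, L);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        long col = oy + (long)OH * (ox + (long)OW * n);
        double* dst = cp + col * K;
        for (int kx = 0; kx < KW; ++kx) {
          int ix = ox * SW - PW + kx * DW;
          for (int ky = 0; ky < KH; ++ky) {
            int iy = oy * SH - PH + ky * DH;
            double* d = dst + (long)C * (ky + (long)KH * kx);
            if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
              std::memcpy(d, xp + idx4(0, iy, ix, n, C, H, W),
                          C * sizeof(double));
            } // else stays zero
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of cpp_im2col: scatter-add columns back into an image tensor
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, int C, int H, int W, int N,
                         int KH, int KW, int SH, int SW, int PH, int PW,
                         int DH, int DW) {
  const int OH = (H + 2 * PH - DH * (KH - 1) - 1) / SH + 1;
  const int OW = (W + 2 * PW - DW * (KW - 1) - 1) / SW + 1;
  NumericVector x((long)C * H * W * N);
  const double* cp = cols.begin();
  double* xp = x.begin();
  const long K = (long)C * KH * KW;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        long col = oy + (long)OH * (ox + (long)OW * n);
        const double* src = cp + col * K;
        for (int kx = 0; kx < KW; ++kx) {
          int ix = ox * SW - PW + kx * DW;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < KH; ++ky) {
            int iy = oy * SH - PH + ky * DH;
            if (iy < 0 || iy >= H) continue;
            const double* s = src + (long)C * (ky + (long)KH * kx);
            double* d = xp + idx4(0, iy, ix, n, C, H, W);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return x;
}

// depthwise convolution forward; weights laid out C x (KH*KW) with column
// index ky + KH*kx
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(const NumericVector& x, const NumericMatrix& w,
                             int C, int H, int W, int N, int KH, int KW,
                             int SH, int SW, int PH, int PW, int DH, int DW) {
  const int OH = (H + 2 * PH - DH * (KH - 1) - 1) / SH + 1;
  const int OW = (W + 2 * PW - DW * (KW - 1) - 1) / SW + 1;
  NumericVector y((long)C * OH * OW * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        double* dst = yp + idx4(0, oy, ox, n, C, OH, OW);
        for (int kx = 0; kx < KW; ++kx) {
          int ix = ox * SW - PW + kx * DW;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < KH; ++ky) {
            int iy = oy * SH - PH + ky * DH;
            if (iy < 0 || iy >= H) continue;
            const double* src = xp + idx4(0, iy, ix, n, C, H, W);
            const double* ww = wp + (long)C * (ky + (long)KH * kx);
            for (int c = 0; c < C; ++c) dst[c] += ww[c] * src[c];
          }
        }
      }
    }
  }
  return y;
}

// depthwise convolution backward: returns dX; fills dW (C x KH*KW) in place
// [[Rcpp::export]]
NumericVector cpp_dwconv_bwd(const NumericVector& x, const NumericMatrix& w,
                             const NumericVector& dy, NumericMatrix& dw,
                             int C, int H, int W, int N, int KH, int KW,
                             int SH, int SW, int PH, int PW, int DH, int DW) {
  const int OH = (H + 2 * PH - DH * (KH - 1) - 1) / SH + 1;
  const int OW = (W + 2 * PW - DW * (KW - 1) - 1) / SW + 1;
  NumericVector dx((long)C * H * W * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const double* g = dyp + idx4(0, oy, ox, n, C, OH, OW);
        for (int kx = 0; kx < KW; ++kx) {
          int ix = ox * SW - PW + kx * DW;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < KH; ++ky) {
            int iy = oy * SH - PH + ky * DH;
            if (iy < 0 || iy >= H) continue;
            const double* src = xp + idx4(0, iy, ix, n, C, H, W);
            double* dsrc = dxp + idx4(0, iy, ix, n, C, H, W);
            const double* ww = wp + (long)C * (ky + (long)KH * kx);
            double* dww = dwp + (long)C * (ky + (long)KH * kx);
            for (int c = 0; c < C; ++c) {
              dsrc[c] += ww[c] * g[c];
              dww[c] += src[c] * g[c];
            }
          }
        }
      }
    }
  }
  return dx;
}

// bilinear resize (half-pixel centres, i.e. align_corners = FALSE)
// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(const NumericVector& x, int C, int H, int W,
                               int N, int OH, int OW) {
  NumericVector y((long)C * OH * OW * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double sh = (double)H / OH, sw = (double)W / OW;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      double fx = (ox + 0.5) * sw - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      for (int oy = 0; oy < OH; ++oy) {
        double fy = (oy + 0.5) * sh - 0.5;
        int y0 = (int)std::floor(fy);
        double wy = fy - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(std::max(y0 + 1, 0), H - 1);
        const double* p00 = xp + idx4(0, y0c, x0c, n, C, H, W);
        const double* p10 = xp + idx4(0, y1c, x0c, n, C, H, W);
        const double* p01 = xp + idx4(0, y0c, x1c, n, C, H, W);
        const double* p11 = xp + idx4(0, y1c, x1c, n, C, H, W);
        double* dst = yp + idx4(0, oy, ox, n, C, OH, OW);
        double w00 = (1 - wy) * (1 - wx), w10 = wy * (1 - wx);
        double w01 = (1 - wy) * wx, w11 = wy * wx;
        for (int c = 0; c < C; ++c) {
          dst[c] = w00 * p00[c] + w10 * p10[c] + w01 * p01[c] + w11 * p11[c];
        }
      }
    }
  }
  return y;
}

// adjoint of cpp_bilinear_fwd
// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(const NumericVector& dy, int C, int H, int W,
                               int N, int OH, int OW) {
  NumericVector dx((long)C * H * W * N);
  const double* gp = dy.begin();
  double* dp = dx.begin();
  const double sh = (double)H / OH, sw = (double)W / OW;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      double fx = (ox + 0.5) * sw - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      for (int oy = 0; oy < OH; ++oy) {
        double fy = (oy + 0.5) * sh - 0.5;
        int y0 = (int)std::floor(fy);
        double wy = fy - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(std::max(y0 + 1, 0), H - 1);
        const double* g = gp + idx4(0, oy, ox, n, C, OH, OW);
        double* p00 = dp + idx4(0, y0c, x0c, n, C, H, W);
        double* p10 = dp + idx4(0, y1c, x0c, n, C, H, W);
        double* p01 = dp + idx4(0, y0c, x1c, n, C, H, W);
        double* p11 = dp + idx4(0, y1c, x1c, n, C, H, W);
        double w00 = (1 - wy) * (1 - wx), w10 = wy * (1 - wx);
        double w01 = (1 - wy) * wx, w11 = wy * wx;
        for (int c = 0; c < C; ++c) {
          p00[c] += w00 * g[c];
          p10[c] += w10 * g[c];
          p01[c] += w01 * g[c];
          p11[c] += w11 * g[c];
        }
      }
    }
  }
  return dx;
}
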
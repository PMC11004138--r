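// Dense conv / pooling / resize kernels for the tile encoder.
// Tensors are column-major numeric arrays with dim (H, W, C, N);
// kernels are (kh, kw, Cin, Cout).  Stride is fixed at 1 with symmetric
// zero padding; pooling is 2x2 average with stride 2.

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector X, NumericVector K, NumericVector b,
                         int pad) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dk = K.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dk[0], kw = dk[1], Ci = dk[2], Co = dk[3];
  if (Ci != C) stop("channel mismatch between input and kernel");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  NumericVector Y(static_cast<R_xlen_t>(Ho) * Wo * Co * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const double *x = X.begin(), *k = K.begin();
  double *y = Y.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double bias = b[co];
      double *yp = y + idx4(0, 0, co, n, Ho, Wo, Co);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) yp[ho + Ho * wo] = bias;
      for (int ci = 0; ci < C; ++ci) {
        const double *xp = x + idx4(0, 0, ci, n, H, W, C);
        for (int dw = 0; dw < kw; ++dw) {
          for (int dh = 0; dh < kh; ++dh) {
            const double kv = k[dh + kh * (dw + kw * (ci + Ci * co))];
            if (kv == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo + dw - pad;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = xp + H * wi;
              double *ycol = yp + Ho * wo;
              const int h0 = std::max(0, pad - dh);
              const int h1 = std::min(Ho, H + pad - dh);
              for (int ho = h0; ho < h1; ++ho)
                ycol[ho] += kv * xcol[ho + dh - pad];
            }
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector X, NumericVector K, NumericVector dY, int pad) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dk = K.attr("dim");
  IntegerVector dy = dY.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dk[0], kw = dk[1], Ci = dk[2], Co = dk[3];
  const int Ho = dy[0], Wo = dy[1];
  NumericVector dX(X.size()), dK(K.size()), db(Co);
  dX.attr("dim") = dx;
  dK.attr("dim") = dk;
  const double *x = X.begin(), *k = K.begin(), *g = dY.begin();
  double *gx = dX.begin(), *gk = dK.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double *gp = g + idx4(0, 0, co, n, Ho, Wo, Co);
      double acc = 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) acc += gp[ho + Ho * wo];
      db[co] += acc;
      for (int ci = 0; ci < C; ++ci) {
        const double *xp = x + idx4(0, 0, ci, n, H, W, C);
        double *gxp = gx + idx4(0, 0, ci, n, H, W, C);
        for (int dw = 0; dw < kw; ++dw) {
          for (int dh = 0; dh < kh; ++dh) {
            const int ki = dh + kh * (dw + kw * (ci + Ci * co));
            const double kv = k[ki];
            double gacc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo + dw - pad;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = xp + H * wi;
              double *gxcol = gxp + H * wi;
              const double *gcol = gp + Ho * wo;
              const int h0 = std::max(0, pad - dh);
              const int h1 = std::min(Ho, H + pad - dh);
              for (int ho = h0; ho < h1; ++ho) {
                const double gv = gcol[ho];
                gacc += gv * xcol[ho + dh - pad];
                gxcol[ho + dh - pad] += gv * kv;
              }
            }
            gk[ki] += gacc;
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dK, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector avgpool2_fwd(NumericVector X) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector Y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *x = X.begin();
  double *y = Y.begin();
  const R_xlen_t planes = static_cast<R_xlen_t>(C) * N;
  for (R_xlen_t p = 0; p < planes; ++p) {
    const double *xp = x + static_cast<R_xlen_t>(H) * W * p;
    double *yp = y + static_cast<R_xlen_t>(Ho) * Wo * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yp[ho + Ho * wo] = 0.25 * (xp[2 * ho + H * (2 * wo)] +
                                   xp[2 * ho + 1 + H * (2 * wo)] +
                                   xp[2 * ho + H * (2 * wo + 1)] +
                                   xp[2 * ho + 1 + H * (2 * wo + 1)]);
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd(NumericVector dY, int H, int W) {
  IntegerVector dy = dY.attr("dim");
  const int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  NumericVector dX(static_cast<R_xlen_t>(H) * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *g = dY.begin();
  double *gx = dX.begin();
  const R_xlen_t planes = static_cast<R_xlen_t>(C) * N;
  for (R_xlen_t p = 0; p < planes; ++p) {
    const double *gp = g + static_cast<R_xlen_t>(Ho) * Wo * p;
    double *gxp = gx + static_cast<R_xlen_t>(H) * W * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double v = 0.25 * gp[ho + Ho * wo];
        gxp[2 * ho + H * (2 * wo)] = v;
        gxp[2 * ho + 1 + H * (2 * wo)] = v;
        gxp[2 * ho + H * (2 * wo + 1)] = v;
        gxp[2 * ho + 1 + H * (2 * wo + 1)] = v;
      }
  }
  return dX;
}

// Bilinear resize of a single (H, W, C) image using the pixel-center
// convention; used by the crop-resize augmentation and tile downsampling.
// [[Rcpp::export]]
NumericVector resize_bilinear(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(static_cast<R_xlen_t>(out_h) * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  const double *x = img.begin();
  double *y = out.begin();
  const double sh = static_cast<double>(H) / out_h;
  const double sw = static_cast<double>(W) / out_w;
  for (int c = 0; c < C; ++c) {
    const double *xp = x + static_cast<R_xlen_t>(H) * W * c;
    double *yp = y + static_cast<R_xlen_t>(out_h) * out_w * c;
    for (int j = 0; j < out_w; ++j) {
      double sj = (j + 0.5) * sw - 0.5;
      if (sj < 0) sj = 0;
      if (sj > W - 1) sj = W - 1;
      const int j0 = static_cast<int>(sj);
      const int j1 = std::min(j0 + 1, W - 1);
      const double fj = sj - j0;
      for (int i = 0; i < out_h; ++i) {
        double si = (i + 0.5) * sh - 0.5;
        if (si < 0) si = 0;
        if (si > H - 1) si = H - 1;
        const int i0 = static_cast<int>(si);
        const int i1 = std::min(i0 + 1, H - 1);
        const double fi = si - i0;
        yp[i + out_h * j] =
            (1 - fi) * ((1 - fj) * xp[i0 + H * j0] + fj * xp[i0 + H * j1]) +
            fi * ((1 - fj) * xp[i1 + H * j0] + fj * xp[i1 + H * j1]);
      }
    }
  }
  return out;
}

// im2col for 3x3-style dense convolution: output matrix has
// Ho*Wo*N rows (ho fastest, then wo, then n) and kh*kw*C columns
// (dh fastest, then dw, then c), matching the column-major flattening
// of a (kh, kw, C, Co) kernel array.
// [[Rcpp::export]]
NumericMatrix im2col(NumericVector X, int kh, int kw, int pad) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const R_xlen_t P = static_cast<R_xlen_t>(Ho) * Wo;
  NumericMatrix out(P * N, kh * kw * C);
  const double *x = X.begin();
  double *o = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int q = dh + kh * (dw + kw * c);
        double *ocol = o + static_cast<R_xlen_t>(q) * P * N;
        for (int n = 0; n < N; ++n) {
          const double *xp = x + idx4(0, 0, c, n, H, W, C);
          double *op = ocol + static_cast<R_xlen_t>(n) * P;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo + dw - pad;
            double *od = op + static_cast<R_xlen_t>(wo) * Ho;
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) od[ho] = 0.0;
              continue;
            }
            const double *xcol = xp + static_cast<R_xlen_t>(wi) * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho + dh - pad;
              od[ho] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col: accumulates a (Ho*Wo*N) x (kh*kw*C)
// gradient matrix back onto the (H, W, C, N) input layout.
// [[Rcpp::export]]
NumericVector col2im_add(NumericMatrix dcol, int H, int W, int C, int N,
                         int kh, int kw, int pad) {
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const R_xlen_t P = static_cast<R_xlen_t>(Ho) * Wo;
  NumericVector dX(static_cast<R_xlen_t>(H) * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *g = dcol.begin();
  double *o = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int q = dh + kh * (dw + kw * c);
        const double *gcol = g + static_cast<R_xlen_t>(q) * P * N;
        for (int n = 0; n < N; ++n) {
          double *op = o + idx4(0, 0, c, n, H, W, C);
          const double *gp = gcol + static_cast<R_xlen_t>(n) * P;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo + dw - pad;
            if (wi < 0 || wi >= W) continue;
            double *ocol = op + static_cast<R_xlen_t>(wi) * H;
            const double *gd = gp + static_cast<R_xlen_t>(wo) * Ho;
            const int h0 = std::max(0, pad - dh);
            const int h1 = std::min(Ho, H + pad - dh);
            for (int ho = h0; ho < h1; ++ho)
              ocol[ho + dh - pad] += gd[ho];
          }
        }
      }
    }
  }
  return dX;
}
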
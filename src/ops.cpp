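#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Feature maps are R arrays in (H, W, C) column-major order.
// im2col lays each receptive field out as one column so convolution becomes
// a single BLAS GEMM: out = W[Cout x k*k*Cin] %*% cols[k*k*Cin x Hout*Wout].
// Row order within a column: kh fastest, then kw, then channel.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  int Hout = (H + 2 * pad - k) / stride + 1;
  int Wout = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(k * k * C, Hout * Wout);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      R_xlen_t col = (R_xlen_t)wo * Hout + ho;
      double *dst = pc + col * (R_xlen_t)(k * k * C);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        R_xlen_t coff = (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          bool win = (w >= 0 && w < W);
          R_xlen_t woff = coff + (R_xlen_t)w * H;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh;
            *dst++ = (win && h >= 0 && h < H) ? px[woff + h] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Hout = (H + 2 * pad - k) / stride + 1;
  int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      R_xlen_t col = (R_xlen_t)wo * Hout + ho;
      const double *src = pc + col * (R_xlen_t)(k * k * C);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        R_xlen_t coff = (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          bool win = (w >= 0 && w < W);
          R_xlen_t woff = coff + (R_xlen_t)w * H;
          for (int kh = 0; kh < k; ++kh, ++src) {
            int h = h0 + kh;
            if (win && h >= 0 && h < H) px[woff + h] += *src;
          }
        }
      }
    }
  }
  return x;
}

// Max-pool, stride 1, odd kernel, same padding. Returns list(value, argmax)
// with 1-based argmax into the flattened input, for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_same(NumericVector x, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * C);
  IntegerVector arg((R_xlen_t)H * W * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    R_xlen_t coff = (R_xlen_t)c * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double best = -DBL_MAX;
        R_xlen_t bidx = 0;
        int wlo = w - pad < 0 ? 0 : w - pad;
        int whi = w + pad >= W ? W - 1 : w + pad;
        int hlo = h - pad < 0 ? 0 : h - pad;
        int hhi = h + pad >= H ? H - 1 : h + pad;
        for (int ww = wlo; ww <= whi; ++ww) {
          R_xlen_t woff = coff + (R_xlen_t)ww * H;
          for (int hh = hlo; hh <= hhi; ++hh) {
            double v = px[woff + hh];
            if (v > best) { best = v; bidx = woff + hh; }
          }
        }
        R_xlen_t o = coff + (R_xlen_t)w * H + h;
        out[o] = best;
        arg[o] = (int)(bidx + 1);
      }
    }
  }
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// Bilinear resize of an (H, W, C) array; used by letterboxing. Pixel centers
// at i+0.5 so the mapping is symmetric and invertible to within a pixel.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H, int W, int C,
                                  int Hout, int Wout) {
  NumericVector out((R_xlen_t)Hout * Wout * C);
  const double *px = x.begin();
  double sy = (double)H / Hout, sx = (double)W / Wout;
  for (int c = 0; c < C; ++c) {
    R_xlen_t ic = (R_xlen_t)c * H * W, oc = (R_xlen_t)c * Hout * Wout;
    for (int w = 0; w < Wout; ++w) {
      double fx = (w + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double ax = fx - x0;
      int x1 = x0 + 1;
      int cx0 = x0 < 0 ? 0 : (x0 >= W ? W - 1 : x0);
      int cx1 = x1 < 0 ? 0 : (x1 >= W ? W - 1 : x1);
      for (int h = 0; h < Hout; ++h) {
        double fy = (h + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(fy);
        double ay = fy - y0;
        int y1 = y0 + 1;
        int cy0 = y0 < 0 ? 0 : (y0 >= H ? H - 1 : y0);
        int cy1 = y1 < 0 ? 0 : (y1 >= H ? H - 1 : y1);
        double v00 = px[ic + (R_xlen_t)cx0 * H + cy0];
        double v01 = px[ic + (R_xlen_t)cx1 * H + cy0];
        double v10 = px[ic + (R_xlen_t)cx0 * H + cy1];
        double v11 = px[ic + (R_xlen_t)cx1 * H + cy1];
        out[oc + (R_xlen_t)w * Hout + h] =
          (1 - ay) * ((1 - ax) * v00 + ax * v01) +
          ay * ((1 - ax) * v10 + ax * v11);
      }
    }
  }
  return out;
}
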
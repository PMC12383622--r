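// Dense tensor kernels for the segmentation network.
// Array layout everywhere: x[h, w, c, b] column-major (R array dim = c(H, W, C, B)).
// Convolutions use zero padding; sampling ops clamp to the border.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t ix4(int h, int w, int c, int b, int H, int W, int C) {
  return h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * b));
}

// ---- standard convolution: im2col + GEMM -----------------------------------

static void im2col(const double* x, int H, int W, int C, int b,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        for (int j = 0; j < Wo; ++j) {
          int ws = j * stride - pad + kj;
          if (ws < 0 || ws >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int hs = i * stride - pad + ki;
            if (hs < 0 || hs >= H) continue;
            col(r, i + (R_xlen_t)Ho * j) = x[ix4(hs, ws, c, b, H, W, C)];
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wgt, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1, Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, L = Ho * Wo;
  arma::mat wmat(const_cast<double*>(wgt.begin()), K, Co, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Co * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, B);
  arma::mat col(K, L);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin(), H, W, C, b, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat o = wmat.t() * col;  // (Co, L)
    double* op = out.begin() + (R_xlen_t)Ho * Wo * Co * b;
    for (int co = 0; co < Co; ++co)
      for (int l = 0; l < L; ++l)
        op[(l % Ho) + (R_xlen_t)Ho * ((l / Ho) + (R_xlen_t)Wo * co)] = o(co, l);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wgt, NumericVector dout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim"), od = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = od[0], Wo = od[1];
  int K = kh * kw * C, L = Ho * Wo;
  arma::mat wmat(const_cast<double*>(wgt.begin()), K, Co, false, true);
  NumericVector dx((R_xlen_t)H * W * C * B), dw((R_xlen_t)K * Co);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dwm(dw.begin(), K, Co, false, true);
  arma::mat col(K, L), dom(Co, L);
  for (int b = 0; b < B; ++b) {
    const double* dp = dout.begin() + (R_xlen_t)Ho * Wo * Co * b;
    for (int co = 0; co < Co; ++co)
      for (int l = 0; l < L; ++l)
        dom(co, l) = dp[(l % Ho) + (R_xlen_t)Ho * ((l / Ho) + (R_xlen_t)Wo * co)];
    im2col(x.begin(), H, W, C, b, kh, kw, stride, pad, Ho, Wo, col);
    dwm += col * dom.t();
    arma::mat dcol = wmat * dom;  // (K, L)
    double* dxb = dx.begin() + (R_xlen_t)H * W * C * b;
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          int r = ki + kh * (kj + kw * c);
          for (int j = 0; j < Wo; ++j) {
            int ws = j * stride - pad + kj;
            if (ws < 0 || ws >= W) continue;
            for (int i = 0; i < Ho; ++i) {
              int hs = i * stride - pad + ki;
              if (hs < 0 || hs >= H) continue;
              dxb[hs + (R_xlen_t)H * (ws + (R_xlen_t)W * c)] += dcol(r, i + (R_xlen_t)Ho * j);
            }
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---- depthwise convolution --------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector wgt, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");  // wgt (kh, kw, C)
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = (H + 2 * pad - kh) / stride + 1, Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* wc = wgt.begin() + (R_xlen_t)kh * kw * c;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double acc = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            int ws = j * stride - pad + kj;
            if (ws < 0 || ws >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int hs = i * stride - pad + ki;
              if (hs < 0 || hs >= H) continue;
              acc += wc[ki + kh * kj] * x[ix4(hs, ws, c, b, H, W, C)];
            }
          }
          out[ix4(i, j, c, b, Ho, Wo, C)] = acc;
        }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector wgt, NumericVector dout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim"), od = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = od[0], Wo = od[1];
  NumericVector dx((R_xlen_t)H * W * C * B), dw((R_xlen_t)kh * kw * C);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* wc = wgt.begin() + (R_xlen_t)kh * kw * c;
      double* dwc = dw.begin() + (R_xlen_t)kh * kw * c;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double g = dout[ix4(i, j, c, b, Ho, Wo, C)];
          if (g == 0.0) continue;
          for (int kj = 0; kj < kw; ++kj) {
            int ws = j * stride - pad + kj;
            if (ws < 0 || ws >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int hs = i * stride - pad + ki;
              if (hs < 0 || hs >= H) continue;
              double xv = x[ix4(hs, ws, c, b, H, W, C)];
              dwc[ki + kh * kj] += g * xv;
              dx[ix4(hs, ws, c, b, H, W, C)] += g * wc[ki + kh * kj];
            }
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---- max pooling ------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1, Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  IntegerVector amax((R_xlen_t)Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -INFINITY;
          int barg = -1;
          for (int kj = 0; kj < k; ++kj) {
            int ws = j * stride - pad + kj;
            if (ws < 0 || ws >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hs = i * stride - pad + ki;
              if (hs < 0 || hs >= H) continue;
              double v = x[ix4(hs, ws, c, b, H, W, C)];
              if (v > best) { best = v; barg = hs + H * ws; }
            }
          }
          R_xlen_t o = ix4(i, j, c, b, Ho, Wo, C);
          out[o] = best;
          amax[o] = barg;
        }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector xdim, IntegerVector amax, NumericVector dout) {
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  IntegerVector od = dout.attr("dim");
  int Ho = od[0], Wo = od[1];
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = xdim;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
      for (R_xlen_t l = 0; l < (R_xlen_t)Ho * Wo; ++l) {
        R_xlen_t o = l + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * b);
        if (amax[o] >= 0) dx[off + amax[o]] += dout[o];
      }
    }
  return dx;
}

// ---- nearest-neighbour 2x upsampling ---------------------------------------

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector out((R_xlen_t)4 * H * W * C * B);
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i)
          out[ix4(i, j, c, b, 2 * H, 2 * W, C)] = x[ix4(i / 2, j / 2, c, b, H, W, C)];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(IntegerVector xdim, NumericVector dout) {
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = xdim;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i)
          dx[ix4(i / 2, j / 2, c, b, H, W, C)] += dout[ix4(i, j, c, b, 2 * H, 2 * W, C)];
  return dx;
}

// ---- adaptive-kernel bilinear resampling ------------------------------------
// For output cell (i, j), sampling point n, the position is
//   (i*stride, j*stride) + Pn[n, ] + offset[i, j, (2n-1, 2n), b]
// clamped to the raster; values are read with bilinear interpolation.
// Output has C*N channels: channel c of point n lands at index c + C*n.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_ak_sample_fwd(NumericVector x, NumericVector off,
                                IntegerMatrix pn, int stride) {
  IntegerVector xd = x.attr("dim"), od = off.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = od[0], Wo = od[1];
  int N = pn.nrow();
  NumericVector out((R_xlen_t)Ho * Wo * C * N * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C * N, B);
  for (int b = 0; b < B; ++b)
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double r = clampd(i * stride + pn(n, 0) + off[ix4(i, j, 2 * n, b, Ho, Wo, od[2])], 0.0, H - 1.0);
          double cpos = clampd(j * stride + pn(n, 1) + off[ix4(i, j, 2 * n + 1, b, Ho, Wo, od[2])], 0.0, W - 1.0);
          int r0 = (int)std::floor(r), c0 = (int)std::floor(cpos);
          int r1 = r0 + 1 < H ? r0 + 1 : r0, c1 = c0 + 1 < W ? c0 + 1 : c0;
          double fr = r - r0, fc = cpos - c0;
          for (int c = 0; c < C; ++c) {
            double v00 = x[ix4(r0, c0, c, b, H, W, C)], v01 = x[ix4(r0, c1, c, b, H, W, C)];
            double v10 = x[ix4(r1, c0, c, b, H, W, C)], v11 = x[ix4(r1, c1, c, b, H, W, C)];
            out[ix4(i, j, c + C * n, b, Ho, Wo, C * N)] =
              (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
          }
        }
  return out;
}

// [[Rcpp::export]]
List cpp_ak_sample_bwd(NumericVector x, NumericVector off, IntegerMatrix pn,
                       int stride, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), od = off.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = od[0], Wo = od[1];
  int N = pn.nrow();
  NumericVector dx((R_xlen_t)H * W * C * B), doff(off.size());
  dx.attr("dim") = xd;
  doff.attr("dim") = od;
  for (int b = 0; b < B; ++b)
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double rr = i * stride + pn(n, 0) + off[ix4(i, j, 2 * n, b, Ho, Wo, od[2])];
          double cc = j * stride + pn(n, 1) + off[ix4(i, j, 2 * n + 1, b, Ho, Wo, od[2])];
          bool rin = rr > 0.0 && rr < H - 1.0, cin = cc > 0.0 && cc < W - 1.0;
          double r = clampd(rr, 0.0, H - 1.0), cpos = clampd(cc, 0.0, W - 1.0);
          int r0 = (int)std::floor(r), c0 = (int)std::floor(cpos);
          int r1 = r0 + 1 < H ? r0 + 1 : r0, c1 = c0 + 1 < W ? c0 + 1 : c0;
          double fr = r - r0, fc = cpos - c0;
          double gr = 0.0, gc = 0.0;
          for (int c = 0; c < C; ++c) {
            double g = dout[ix4(i, j, c + C * n, b, Ho, Wo, C * N)];
            if (g == 0.0) continue;
            double v00 = x[ix4(r0, c0, c, b, H, W, C)], v01 = x[ix4(r0, c1, c, b, H, W, C)];
            double v10 = x[ix4(r1, c0, c, b, H, W, C)], v11 = x[ix4(r1, c1, c, b, H, W, C)];
            dx[ix4(r0, c0, c, b, H, W, C)] += g * (1 - fr) * (1 - fc);
            dx[ix4(r0, c1, c, b, H, W, C)] += g * (1 - fr) * fc;
            dx[ix4(r1, c0, c, b, H, W, C)] += g * fr * (1 - fc);
            dx[ix4(r1, c1, c, b, H, W, C)] += g * fr * fc;
            gr += g * ((1 - fc) * (v10 - v00) + fc * (v11 - v01));
            gc += g * ((1 - fr) * (v01 - v00) + fr * (v11 - v10));
          }
          if (rin) doff[ix4(i, j, 2 * n, b, Ho, Wo, od[2])] = gr;
          if (cin) doff[ix4(i, j, 2 * n + 1, b, Ho, Wo, od[2])] = gc;
        }
  return List::create(_["dx"] = dx, _["doff"] = doff);
}

// Bilinear read at arbitrary (row, col) positions with border clamp;
// pts is an n x 2 matrix of 0-based fractional coordinates.
// [[Rcpp::export]]
NumericVector cpp_bilinear_at(NumericMatrix x, NumericMatrix pts) {
  int H = x.nrow(), W = x.ncol(), n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double r = clampd(pts(q, 0), 0.0, H - 1.0), c = clampd(pts(q, 1), 0.0, W - 1.0);
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = r0 + 1 < H ? r0 + 1 : r0, c1 = c0 + 1 < W ? c0 + 1 : c0;
    double fr = r - r0, fc = c - c0;
    out[q] = (1 - fr) * ((1 - fc) * x(r0, c0) + fc * x(r0, c1)) +
             fr * ((1 - fc) * x(r1, c0) + fc * x(r1, c1));
  }
  return out;
}
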
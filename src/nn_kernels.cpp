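// Convolution kernels for the tiny CNN framework.
//
// Tensor layout follows R's column-major arrays: dim = (H, W, C, N),
// i.e. x[h + H*(w + W*(c + C*n))]. Weights: dim = (kh, kw, Cin, Cout).
// The whole batch is lowered into one tall im2col matrix (P*N x K) so each
// layer costs a single GEMM per pass (BLAS via arma::mat).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill rows [P*n, P*n+P) of `col` (P*N x K) from sample n.
// Row p = oh + oH*ow; column k = i + kh*(j + kw*c).
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int oH, int oW, arma::mat& col, int row0) {
  int P = oH * oW;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int k = i + kh * (j + kw * c);
        double* dst = col.colptr(k) + row0;
        for (int ow = 0; ow < oW; ++ow) {
          int w_in = ow * stride - pad + j;
          if (w_in < 0 || w_in >= W) {
            for (int oh = 0; oh < oH; ++oh) dst[oh + oH * ow] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * w_in;
          for (int oh = 0; oh < oH; ++oh) {
            int h_in = oh * stride - pad + i;
            dst[oh + oH * ow] = (h_in < 0 || h_in >= H) ? 0.0 : xcol[h_in];
          }
        }
      }
    }
  }
  (void)P;
}

// Scatter-add rows [row0, row0+P) of dcol back into dx for one sample.
static void col2im(const arma::mat& dcol, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int oH, int oW, double* dx, int row0) {
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int k = i + kh * (j + kw * c);
        const double* src = dcol.colptr(k) + row0;
        for (int ow = 0; ow < oW; ++ow) {
          int w_in = ow * stride - pad + j;
          if (w_in < 0 || w_in >= W) continue;
          double* xcol = xc + (size_t)H * w_in;
          for (int oh = 0; oh < oH; ++oh) {
            int h_in = oh * stride - pad + i;
            if (h_in >= 0 && h_in < H) xcol[h_in] += src[oh + oH * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight Cin mismatch");
  int oH = out_size(H, kh, stride, pad), oW = out_size(W, kw, stride, pad);
  if (oH < 1 || oW < 1) stop("conv2d: output would be empty");
  int K = kh * kw * Cin, P = oH * oW;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(P * N, K);
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
           kh, kw, stride, pad, oH, oW, col, P * n);
  arma::mat ym = col * Wm;  // (P*N) x Cout

  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(oH, oW, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = ym.colptr(co) + (size_t)P * n;
      double* dst = y.begin() + (size_t)P * (co + (size_t)Cout * n);
      double bc = b[co];
      for (int p = 0; p < P; ++p) dst[p] = src[p] + bc;
    }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int oH = yd[0], oW = yd[1];
  int K = kh * kw * Cin, P = oH * oW;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(P * N, K);
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
           kh, kw, stride, pad, oH, oW, col, P * n);

  // reorder dy (oH,oW,Cout,N) -> (P*N) x Cout
  arma::mat dym(P * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + (size_t)P * (co + (size_t)Cout * n);
      double* dst = dym.colptr(co) + (size_t)P * n;
      std::copy(src, src + P, dst);
    }

  NumericVector dwv((size_t)K * Cout);
  dwv.attr("dim") = wd;
  arma::mat dW(dwv.begin(), K, Cout, false, true);
  dW = col.t() * dym;

  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = arma::accu(dym.col(co));

  NumericVector dxv;
  if (need_dx) {
    dxv = NumericVector((size_t)H * W * Cin * N);
    dxv.attr("dim") = xd;
    arma::mat dcol = dym * Wm.t();  // (P*N) x K
    for (int n = 0; n < N; ++n)
      col2im(dcol, H, W, Cin, kh, kw, stride, pad, oH, oW,
             dxv.begin() + (size_t)H * W * Cin * n, P * n);
  }
  return List::create(_["dw"] = dwv, _["db"] = dbv,
                      _["dx"] = need_dx ? (SEXP)dxv : R_NilValue);
}

// Leaky ReLU forward (slope 0.2) and its mask, fused to avoid R ifelse().
// [[Rcpp::export(name = ".lrelu_fwd")]]
List lrelu_fwd(NumericVector x, bool need_grad) {
  size_t n = x.size();
  NumericVector y(n);
  y.attr("dim") = x.attr("dim");
  NumericVector g;
  if (need_grad) {
    g = NumericVector(n);
    g.attr("dim") = x.attr("dim");
  }
  for (size_t i = 0; i < n; ++i) {
    double v = x[i];
    if (v > 0) {
      y[i] = v;
      if (need_grad) g[i] = 1.0;
    } else {
      y[i] = 0.2 * v;
      if (need_grad) g[i] = 0.2;
    }
  }
  return List::create(_["y"] = y, _["g"] = need_grad ? (SEXP)g : R_NilValue);
}
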
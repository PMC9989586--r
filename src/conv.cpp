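#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensors are R arrays in H x W x C x N layout (column-major: h fastest).
// Convolution kernels are kh x kw x Cin x Cout.
// im2col row ordering is (i, j, c) with i fastest, which matches a flat
// reshape of the kernel array, so the GEMM needs no explicit repacking.

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& col) {
  // col: (kh*kw*C) x (Ho*Wo), spatial column index = ho + Ho*wo
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo * stride - pad + j * dil;
          double* dst = col.colptr(0) + r; // row r, walk columns
          if (iw < 0 || iw >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(r, ho + Ho * wo) = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            int ih = ho * stride - pad + i * dil;
            col(r, ho + Ho * wo) =
              (ih >= 0 && ih < H) ? xc[ih + (size_t)H * iw] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo * stride - pad + j * dil;
          if (iw < 0 || iw >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int ih = ho * stride - pad + i * dil;
            if (ih >= 0 && ih < H)
              gc[ih + (size_t)H * iw] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = out_size(H, kh, stride, pad, dil);
  int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: spatial size smaller than dilated kernel extent");

  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  bool has_bias = bias.size() > 0;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat Y = Wm.t() * col; // Cout x (Ho*Wo)
    double* yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double b = has_bias ? bias[co] : 0.0;
      for (int s = 0; s < Ho * Wo; ++s)
        yp[s + (size_t)Ho * Wo * co] = Y(co, s) + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];

  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  arma::mat gWm(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gb(has_bias ? Cout : 0);

  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat gY(Cout, (size_t)Ho * Wo);
    const double* gp = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int s = 0; s < Ho * Wo; ++s)
        gY(co, s) = gp[s + (size_t)Ho * Wo * co];
    gWm += col * gY.t();
    arma::mat gcol = Wm * gY;
    col2im(gcol, H, W, C, kh, kw, stride, pad, dil, Ho, Wo,
           gx.begin() + (size_t)H * W * C * n);
    if (has_bias)
      for (int co = 0; co < Cout; ++co)
        gb[co] += arma::accu(gY.row(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
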
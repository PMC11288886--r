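// im2col-based 2D convolution forward/backward.
// Layout conventions (R column-major):
//   images  x : H x W x C x N
//   kernels W : kh x kw x Cin x Cout
//   outputs y : Ho x Wo x Cout x N
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &a, int d[4]) {
  IntegerVector dd = a.attr("dim");
  if (dd.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// Fill the im2col matrix for one sample.
// cols: (kh*kw*Cin) x (Ho*Wo); column index = oi + Ho*oj.
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat &cols) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int wj = oj * stride + kj - pad;
          for (int oi = 0; oi < Ho; ++oi) {
            int wi = oi * stride + ki - pad;
            double v = 0.0;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              v = xc[wi + (size_t)wj * H];
            cols(row, oi + (size_t)oj * Ho) = v;
          }
        }
      }
    }
  }
}

// Scatter-add of the column gradient back to image space.
static void col2im(const arma::mat &dcols, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *dxc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          int wj = oj * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int wi = oi * stride + ki - pad;
            if (wi < 0 || wi >= H) continue;
            dxc[wi + (size_t)wj * H] += dcols(row, oi + (size_t)oj * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector Wk,
                             NumericVector b, int stride, int pad) {
  int dx4[4], dw4[4];
  get_dims4(x, dx4); get_dims4(Wk, dw4);
  int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  int kh = dw4[0], kw = dw4[1], Cin = dw4[2], Cout = dw4[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");

  int K = kh * kw * Cin;
  arma::mat Wm(K, Cout);
  for (int oc = 0; oc < Cout; ++oc)
    for (int r = 0; r < K; ++r)
      Wm(r, oc) = Wk[r + (size_t)K * oc];

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(K, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat Y = cols.t() * Wm;  // (Ho*Wo) x Cout
    double *yn = &y[0] + (size_t)n * Ho * Wo * Cout;
    for (int oc = 0; oc < Cout; ++oc) {
      double bo = b[oc];
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        yn[p + (size_t)oc * Ho * Wo] = Y(p, oc) + bo;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector Wk, NumericVector dy,
                    int stride, int pad) {
  int dx4[4], dw4[4], dy4[4];
  get_dims4(x, dx4); get_dims4(Wk, dw4); get_dims4(dy, dy4);
  int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  int kh = dw4[0], kw = dw4[1], Cin = dw4[2], Cout = dw4[3];
  int Ho = dy4[0], Wo = dy4[1];
  if (dy4[2] != Cout || dy4[3] != N) stop("conv2d backward: dy shape mismatch");

  int K = kh * kw * Cin;
  arma::mat Wm(K, Cout);
  for (int oc = 0; oc < Cout; ++oc)
    for (int r = 0; r < K; ++r)
      Wm(r, oc) = Wk[r + (size_t)K * oc];

  arma::mat dWm(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat cols(K, (size_t)Ho * Wo);
  arma::mat D((size_t)Ho * Wo, Cout);

  for (int n = 0; n < N; ++n) {
    const double *dyn = &dy[0] + (size_t)n * Ho * Wo * Cout;
    for (int oc = 0; oc < Cout; ++oc)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        D(p, oc) = dyn[p + (size_t)oc * Ho * Wo];
    im2col(&x[0] + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, cols);
    dWm += cols * D;
    db += arma::sum(D, 0).t();
    arma::mat dcols = Wm * D.t();  // K x (Ho*Wo)
    col2im(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo, &dx[0] + (size_t)n * H * W * C);
  }

  NumericVector dWout((size_t)K * Cout);
  dWout.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  for (int oc = 0; oc < Cout; ++oc)
    for (int r = 0; r < K; ++r)
      dWout[r + (size_t)K * oc] = dWm(r, oc);
  NumericVector dbout(Cout);
  for (int oc = 0; oc < Cout; ++oc) dbout[oc] = db(oc);

  return List::create(_["dx"] = dx, _["dW"] = dWout, _["db"] = dbout);
}
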
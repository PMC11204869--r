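// Convolution kernels for the hand-authored network stack.
// Layout convention (column-major R arrays): activations are H x W x C x N;
// a conv weight is a Cout x (C*k*k) matrix whose column index is
// c + C*(di + k*dj) (input channel fastest, then kernel row, then kernel
// column). Stride 1, zero padding (k-1)/2, "same" spatial output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col, transposed layout: (H*W*N) x (C*k*k); row = i + H*(j + W*n).
static arma::mat im2col_t(const double* x, int H, int W, int C, int N, int k) {
  const int p = (k - 1) / 2;
  arma::mat out((size_t)H * W * N, (size_t)C * k * k, arma::fill::zeros);
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di)
      for (int c = 0; c < C; ++c) {
        const size_t col = c + (size_t)C * (di + k * dj);
        double* dst0 = out.colptr(col);
        for (int n = 0; n < N; ++n)
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - p;
            if (jj < 0 || jj >= W) continue;
            const double* src =
                x + (size_t)H * (jj + (size_t)W * (c + (size_t)C * n));
            double* dst = dst0 + (size_t)H * (j + (size_t)W * n);
            const int i0 = std::max(0, p - di);
            const int i1 = std::min(H, H + p - di);
            for (int i = i0; i < i1; ++i) dst[i] = src[i + di - p];
          }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector dims,
                           NumericMatrix Wm, NumericVector b, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = Wm.nrow();
  arma::mat Xt = im2col_t(x.begin(), H, W, C, N, k);
  const arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat Yt = Xt * Wa.t(); // (H*W*N) x Cout
  const arma::rowvec bv(const_cast<double*>(b.begin()), b.size(), false);
  Yt.each_row() += bv;
  NumericVector y((size_t)H * W * Cout * N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = Yt.colptr(co) + HW * n;
      std::copy(src, src + HW, y.begin() + HW * (co + (size_t)Cout * n));
    }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector dims, NumericVector dy,
                  NumericMatrix Wm, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = Wm.nrow();
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  arma::mat Xt = im2col_t(x.begin(), H, W, C, N, k);
  arma::mat dYt((size_t)H * W * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + HW * (co + (size_t)Cout * n);
      std::copy(src, src + HW, dYt.colptr(co) + HW * n);
    }
  const arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat dW = dYt.t() * Xt;
  arma::vec db = arma::sum(dYt, 0).t();
  arma::mat dXt = dYt * Wa; // (H*W*N) x (C*k*k)
  NumericVector dx((size_t)H * W * C * N); // zero-initialized
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di)
      for (int c = 0; c < C; ++c) {
        const size_t col = c + (size_t)C * (di + k * dj);
        const double* src0 = dXt.colptr(col);
        for (int n = 0; n < N; ++n)
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - p;
            if (jj < 0 || jj >= W) continue;
            double* dst =
                dx.begin() + (size_t)H * (jj + (size_t)W * (c + (size_t)C * n));
            const double* src = src0 + (size_t)H * (j + (size_t)W * n);
            const int i0 = std::max(0, p - di);
            const int i1 = std::min(H, H + p - di);
            for (int i = i0; i < i1; ++i) dst[i + di - p] += src[i];
          }
      }
  dx.attr("dim") = dims;
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}
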
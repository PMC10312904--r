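#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Minimal 2-D convolution kernels for the score network: same-padding
// direct convolution done as im2col + GEMM, with the exact reverse pass.
// Arithmetic is single precision internally (standard for convolutional
// networks, and twice the GEMM throughput); inputs and outputs are R
// doubles.
//
// Layouts (all column-major, matching R arrays):
//   x  : H x W x Cin x N   (NumericVector with a dim attribute)
//   w  : (k*k*Cin) x Cout  weight matrix; row index = c*k*k + kx*k + ky,
//        i.e. channel-major, then kernel column, then kernel row
//   y  : H x W x Cout x N
// k is odd; zero padding of (k-1)/2 keeps the spatial size. The patch
// matrix is laid out (H*W) x (k*k*Cin) so that the output-pixel index is
// the contiguous dimension: both the gather and the scatter then run over
// contiguous spans of image columns.

using arma::fmat;
using arma::fvec;
using Rcpp::NumericVector;
using Rcpp::List;

// colT: (H*W) x (k*k*C); column r = c*k*k + kx*k + ky holds, for each
// output pixel, the input value offset by (ky - pad, kx - pad) in channel c.
static void im2colT(const double* x, int H, int W, int C, int k, fmat& colT) {
  const int pad = (k - 1) / 2;
  colT.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        float* dst0 = colT.colptr(c * k * k + kx * k + ky);
        const int dr = ky - pad, dc = kx - pad;
        const int cc0 = std::max(0, -dc), cc1 = std::min(W, W - dc);
        const int rr0 = std::max(0, -dr), rr1 = std::min(H, H - dr);
        for (int cc = cc0; cc < cc1; ++cc) {
          const double* src = xc + (size_t)(cc + dc) * H + dr;
          float* dst = dst0 + (size_t)cc * H;
          for (int rr = rr0; rr < rr1; ++rr) dst[rr] = (float)src[rr];
        }
      }
    }
  }
}

static void col2imT_add(double* x, const fmat& colT, int H, int W, int C,
                        int k) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const float* src0 = colT.colptr(c * k * k + kx * k + ky);
        const int dr = ky - pad, dc = kx - pad;
        const int cc0 = std::max(0, -dc), cc1 = std::min(W, W - dc);
        const int rr0 = std::max(0, -dr), rr1 = std::min(H, H - dr);
        for (int cc = cc0; cc < cc1; ++cc) {
          double* dst = xc + (size_t)(cc + dc) * H + dr;
          const float* src = src0 + (size_t)cc * H;
          for (int rr = rr0; rr < rr1; ++rr) dst[rr] += src[rr];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, const arma::mat& w,
                             const arma::vec& b, int k) {
  Rcpp::IntegerVector dim = x.attr("dim");
  const int H = dim[0], W = dim[1], C = dim[2];
  const int N = dim.size() > 3 ? dim[3] : 1;
  const int Cout = w.n_cols;
  const fmat wf = arma::conv_to<fmat>::from(w);
  const fvec bf = arma::conv_to<fvec>::from(b);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = Rcpp::IntegerVector::create(H, W, Cout, N);
  fmat colT(H * W, k * k * C);
  for (int nn = 0; nn < N; ++nn) {
    im2colT(x.begin() + (size_t)nn * H * W * C, H, W, C, k, colT);
    fmat out = colT * wf;             // (H*W) x Cout
    out.each_row() += bf.t();
    double* yp = y.begin() + (size_t)nn * H * W * Cout;
    const float* op = out.memptr();
    for (size_t i = 0; i < (size_t)H * W * Cout; ++i) yp[i] = op[i];
  }
  return y;
}

// Reverse pass: given dL/dy, accumulate dL/dw, dL/db over the batch and
// return dL/dx with the transposed (full-correlation) scatter.
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, const arma::mat& w, NumericVector dy,
                    int k) {
  Rcpp::IntegerVector dim = x.attr("dim");
  const int H = dim[0], W = dim[1], C = dim[2];
  const int N = dim.size() > 3 ? dim[3] : 1;
  const int Cout = w.n_cols;
  const fmat wf = arma::conv_to<fmat>::from(w);
  fmat dwf(w.n_rows, Cout, arma::fill::zeros);
  fvec dbf(Cout, arma::fill::zeros);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  fmat colT(H * W, k * k * C);
  fmat dym(H * W, Cout);
  for (int nn = 0; nn < N; ++nn) {
    im2colT(x.begin() + (size_t)nn * H * W * C, H, W, C, k, colT);
    const double* dyp = dy.begin() + (size_t)nn * H * W * Cout;
    float* dp = dym.memptr();
    for (size_t i = 0; i < (size_t)H * W * Cout; ++i) dp[i] = (float)dyp[i];
    dwf += colT.t() * dym;
    dbf += arma::sum(dym, 0).t();
    fmat dcolT = dym * wf.t();        // (H*W) x (k*k*C)
    col2imT_add(dx.begin() + (size_t)nn * H * W * C, dcolT, H, W, C, k);
  }
  return List::create(
    Rcpp::Named("dx") = dx,
    Rcpp::Named("dw") = arma::conv_to<arma::mat>::from(dwf),
    Rcpp::Named("db") = arma::conv_to<arma::vec>::from(dbf));
}
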
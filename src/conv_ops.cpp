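// Compiled kernels for the 3x3 same-padding convolution, the single hot
// spot of the network engine.  Activations are (N*H*W) x C matrices with
// rows ordered image-major then row-major (see R/nn-ops.R); the patch
// matrix P is (N*H*W) x (9*C) with column block k holding the input
// shifted by kernel offset k (zero padding).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void build_patches(const arma::mat& x, arma::mat& P,
                          const int H, const int W, const int N) {
  const int HW = H * W;
  const int C = x.n_cols;
  int k = 0;
  for (int dy = -1; dy <= 1; ++dy) {
    for (int dx = -1; dx <= 1; ++dx, ++k) {
      for (int ci = 0; ci < C; ++ci) {
        double* dst = P.colptr((std::size_t)k * C + ci);
        const double* src = x.colptr(ci);
        for (int n = 0; n < N; ++n) {
          const double* s = src + (std::size_t)n * HW;
          double* d = dst + (std::size_t)n * HW;
          for (int r = 0; r < H; ++r) {
            double* drow = d + (std::size_t)r * W;
            const int sr = r + dy;
            if (sr < 0 || sr >= H) { std::fill(drow, drow + W, 0.0); continue; }
            const double* srow = s + (std::size_t)sr * W;
            const int c0 = std::max(0, -dx);
            const int c1 = std::min(W, W - dx);
            if (c0 > 0) std::fill(drow, drow + c0, 0.0);
            if (c1 < W) std::fill(drow + c1, drow + W, 0.0);
            std::copy(srow + c0 + dx, srow + c1 + dx, drow + c0);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const arma::mat& Wm,
                        const arma::vec& b, const int H, const int W,
                        const int N) {
  const int C = x.n_cols;
  arma::mat P(x.n_rows, 9 * C);
  build_patches(x, P, H, W, N);
  arma::mat y = P * Wm;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& dy, const arma::mat& x,
                   const arma::mat& Wm, const int H, const int W,
                   const int N, const bool need_dx) {
  const int HW = H * W;
  const int C = x.n_cols;
  arma::mat P(x.n_rows, 9 * C);
  build_patches(x, P, H, W, N);
  arma::mat dW = P.t() * dy;
  arma::rowvec db = arma::sum(dy, 0);
  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  arma::mat dP = dy * Wm.t();
  arma::mat dx(x.n_rows, C, arma::fill::zeros);
  // scatter-add: output row (r, c) of offset block k came from input row
  // (r + dy, c + dx); accumulate dP back onto that source row.
  int k = 0;
  for (int ody = -1; ody <= 1; ++ody) {
    for (int odx = -1; odx <= 1; ++odx, ++k) {
      for (int ci = 0; ci < C; ++ci) {
        const double* src = dP.colptr((std::size_t)k * C + ci);
        double* dst = dx.colptr(ci);
        for (int n = 0; n < N; ++n) {
          const double* s = src + (std::size_t)n * HW;
          double* d = dst + (std::size_t)n * HW;
          for (int r = 0; r < H; ++r) {
            const int tr = r + ody;
            if (tr < 0 || tr >= H) continue;
            const double* srow = s + (std::size_t)r * W;
            double* drow = d + (std::size_t)tr * W;
            const int c0 = std::max(0, -odx);
            const int c1 = std::min(W, W - odx);
            for (int c = c0; c < c1; ++c) drow[c + odx] += srow[c];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
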
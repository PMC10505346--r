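// Dense 2-D convolution core: im2col + BLAS GEMM, with the exact adjoint
// (col2im) for the backward pass.  Arrays use the package's H x W x C x N
// column-major layout; kernel weights arrive flattened as a
// (K*K*C_in) x C_out matrix whose row order matches R's column-major
// flattening of a (K, K, C_in, C_out) array.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int K, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& col) {
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int p = io + Ho * jo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
          const int j = jo * stride - pad + kj * dil;
          const bool jok = (j >= 0 && j < W);
          for (int ki = 0; ki < K; ++ki) {
            const int i = io * stride - pad + ki * dil;
            const int r = ki + K * (kj + K * c);
            col(r, p) = (jok && i >= 0 && i < H)
              ? x[i + H * (j + (size_t)W * c)] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(double* gx, int H, int W, int C,
                       int K, int stride, int pad, int dil,
                       int Ho, int Wo, const arma::mat& gcol) {
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int p = io + Ho * jo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
          const int j = jo * stride - pad + kj * dil;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int i = io * stride - pad + ki * dil;
            if (i < 0 || i >= H) continue;
            const int r = ki + K * (kj + K * c);
            gx[i + H * (j + (size_t)W * c)] += gcol(r, p);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            const arma::mat& w, NumericVector b,
                            int kernel, int stride, int pad, int dil) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = kernel, Cout = (int)w.n_cols;
  const int span = dil * (K - 1) + 1;
  const int Ho = (H + 2 * pad - span) / stride + 1;
  const int Wo = (W + 2 * pad - span) / stride + 1;
  if (Ho < 1 || Wo < 1)
    stop("input %dx%d smaller than the dilated kernel footprint %dx%d",
         H, W, span, span);
  const int P = Ho * Wo;
  NumericVector out((R_xlen_t)P * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K * K * C, P);
  const arma::mat wt = w.t();            // Cout x (K*K*C)
  const bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(&x[(size_t)H * W * C * n], H, W, C, K, stride, pad, dil, Ho, Wo, col);
    arma::mat y = wt * col;              // Cout x P
    double* o = &out[(size_t)P * Cout * n];
    for (int oc = 0; oc < Cout; ++oc) {
      const double bb = has_b ? b[oc] : 0.0;
      for (int p = 0; p < P; ++p) o[p + (size_t)P * oc] = y(oc, p) + bb;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   const arma::mat& w, NumericVector gy,
                   int kernel, int stride, int pad, int dil,
                   bool need_gx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = kernel, Cout = (int)w.n_cols;
  const int span = dil * (K - 1) + 1;
  const int Ho = (H + 2 * pad - span) / stride + 1;
  const int Wo = (W + 2 * pad - span) / stride + 1;
  const int P = Ho * Wo;
  arma::mat gw(K * K * C, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx(need_gx ? (R_xlen_t)H * W * C * N : (R_xlen_t)0);
  arma::mat col(K * K * C, P);
  arma::mat gym(Cout, P);
  for (int n = 0; n < N; ++n) {
    const double* g = &gy[(size_t)P * Cout * n];
    for (int oc = 0; oc < Cout; ++oc)
      for (int p = 0; p < P; ++p) gym(oc, p) = g[p + (size_t)P * oc];
    im2col(&x[(size_t)H * W * C * n], H, W, C, K, stride, pad, dil, Ho, Wo, col);
    gw += col * gym.t();
    gb += arma::sum(gym, 1);
    if (need_gx) {
      arma::mat gcol = w * gym;          // (K*K*C) x P
      col2im_add(&gx[(size_t)H * W * C * n], H, W, C, K, stride, pad, dil,
                 Ho, Wo, gcol);
    }
  }
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["gw"] = gw, _["gb"] = NumericVector(gb.begin(), gb.end()),
                      _["gx"] = gx);
}
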
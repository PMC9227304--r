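// Numeric kernels: IIR filtering and the convolution / capsule-transform
// passes of the network. Layout conventions (all 0-based here):
//   * a feature map of H x W x C is stored per sample as a row vector with
//     index h + H*(w + W*c)  (i.e. an R array of dim c(H, W, C));
//   * conv weights are a (K*K*Cin) x Cout matrix, row index
//     kr + K*(kc + K*ci);
//   * primary-capsule activations are rows of length I*Dk with index
//     k + Dk*i (capsule i's Dk components contiguous);
//   * transformation weights W_ij form an array of dim c(D, Dk, J, I);
//   * prediction vectors u_hat are rows of length I*D*J with index
//     i + I*(d + D*j)  (an R array of dim c(I, D, J)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form-II-transposed recursive filter with initial state zi
// (length(b) == length(a), a[0] == 1).
// [[Rcpp::export]]
NumericVector cpp_lfilter(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  const int n = b.size();
  const int m = x.size();
  NumericVector y(m);
  std::vector<double> z(zi.begin(), zi.end());
  for (int t = 0; t < m; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + (n > 1 ? z[0] : 0.0);
    for (int k = 0; k + 2 < n; ++k)
      z[k] = b[k + 1] * xt + z[k + 1] - a[k + 1] * yt;
    if (n > 1)
      z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}

static arma::umat im2col_index(int H, int W, int C, int K, int stride,
                               int Ho, int Wo) {
  arma::umat idx(Ho * Wo, K * K * C);
  for (int c = 0; c < C; ++c)
    for (int kc = 0; kc < K; ++kc)
      for (int kr = 0; kr < K; ++kr) {
        const int col = kr + K * (kc + K * c);
        for (int ow = 0; ow < Wo; ++ow)
          for (int oh = 0; oh < Ho; ++oh) {
            const int r = oh * stride + kr;
            const int cc = ow * stride + kc;
            idx(oh + Ho * ow, col) = r + H * (cc + W * c);
          }
      }
  return idx;
}

// Valid (unpadded) 2-D convolution over a batch, via im2col + GEMM.
// [[Rcpp::export]]
arma::mat cpp_conv2d_fwd(const arma::mat& x, const arma::mat& w,
                         const arma::vec& bias,
                         int H, int W, int C, int K, int stride) {
  const int B = x.n_rows;
  const int Ho = (H - K) / stride + 1;
  const int Wo = (W - K) / stride + 1;
  const int Cout = w.n_cols;
  const int P = Ho * Wo, Q = K * K * C;
  const arma::umat idx = im2col_index(H, W, C, K, stride, Ho, Wo);
  arma::mat y(B, P * Cout);
  arma::mat patch(P, Q);
  arma::rowvec xb;
  for (int b = 0; b < B; ++b) {
    xb = x.row(b);
    for (int q = 0; q < Q; ++q)
      for (int p = 0; p < P; ++p)
        patch(p, q) = xb[idx(p, q)];
    arma::mat out = patch * w;
    out.each_row() += bias.t();
    y.row(b) = arma::vectorise(out).t();
  }
  return y;
}

// Gradients of the valid convolution w.r.t. input, weights, bias.
// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::mat& x, const arma::mat& w,
                    const arma::mat& dy,
                    int H, int W, int C, int K, int stride) {
  const int B = x.n_rows;
  const int Ho = (H - K) / stride + 1;
  const int Wo = (W - K) / stride + 1;
  const int Cout = w.n_cols;
  const int P = Ho * Wo, Q = K * K * C;
  const arma::umat idx = im2col_index(H, W, C, K, stride, Ho, Wo);
  arma::mat dw(Q, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dx(B, H * W * C, arma::fill::zeros);
  arma::mat patch(P, Q);
  arma::rowvec xb, dxb(H * W * C);
  for (int b = 0; b < B; ++b) {
    xb = x.row(b);
    for (int q = 0; q < Q; ++q)
      for (int p = 0; p < P; ++p)
        patch(p, q) = xb[idx(p, q)];
    arma::mat dyb(const_cast<double*>(dy.row(b).eval().memptr()), P, Cout,
                  true, false);
    dw += patch.t() * dyb;
    db += arma::sum(dyb, 0).t();
    arma::mat dpatch = dyb * w.t();
    dxb.zeros();
    for (int q = 0; q < Q; ++q)
      for (int p = 0; p < P; ++p)
        dxb[idx(p, q)] += dpatch(p, q);
    dx.row(b) = dxb;
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// u_hat[b, i, j, .] = W_ij (D x Dk)  %*%  u[b, i, .] (Dk).
// [[Rcpp::export]]
arma::mat cpp_caps_fwd(const arma::mat& u, const arma::vec& Wt,
                       int I, int J, int D, int Dk) {
  const int B = u.n_rows;
  arma::mat uhat(B, (size_t)I * D * J);
  const double* Wp = Wt.memptr();
  std::vector<double> ub(Dk);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < I; ++i) {
      for (int k = 0; k < Dk; ++k) ub[k] = u(b, k + Dk * i);
      for (int j = 0; j < J; ++j) {
        const double* Wij = Wp + (size_t)D * Dk * (j + (size_t)J * i);
        for (int d = 0; d < D; ++d) {
          double acc = 0.0;
          for (int k = 0; k < Dk; ++k) acc += Wij[d + D * k] * ub[k];
          uhat(b, (size_t)i + (size_t)I * (d + D * j)) = acc;
        }
      }
    }
  }
  return uhat;
}

// Adjoint of cpp_caps_fwd: accumulates dW over the batch and returns du.
// [[Rcpp::export]]
List cpp_caps_bwd(const arma::mat& u, const arma::vec& Wt,
                  const arma::mat& duhat,
                  int I, int J, int D, int Dk) {
  const int B = u.n_rows;
  arma::mat du(B, (size_t)I * Dk, arma::fill::zeros);
  arma::vec dW(Wt.n_elem, arma::fill::zeros);
  const double* Wp = Wt.memptr();
  double* dWp = dW.memptr();
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < I; ++i) {
      for (int j = 0; j < J; ++j) {
        const size_t off = (size_t)D * Dk * (j + (size_t)J * i);
        const double* Wij = Wp + off;
        double* dWij = dWp + off;
        for (int d = 0; d < D; ++d) {
          const double g = duhat(b, (size_t)i + (size_t)I * (d + D * j));
          if (g == 0.0) continue;
          for (int k = 0; k < Dk; ++k) {
            dWij[d + D * k] += g * u(b, k + Dk * i);
            du(b, k + Dk * i) += g * Wij[d + D * k];
          }
        }
      }
    }
  }
  return List::create(Named("du") = du, Named("dW") = dW);
}
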
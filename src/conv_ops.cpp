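// Hot kernels for the compact sleep-scoring CNN: 3x3 same-padded
// convolution (as im2col + GEMM), 2x2/stride-2 max pooling, and fused
// batchnorm+ReLU, forward and backward. Activations are (channels x
// H*W*batch) matrices with spatial index s = h + H*w + H*W*b (0-based,
// h fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Patch matrix transposed for write contiguity: P_t is (HWB x 9C) with
// column r = c + C*(dy + 3*dx) holding, per output position s, the input
// value of channel c at offset (dy-1, dx-1). Zero padding stays zero.
static mat im2col3x3_t(const mat& A, int H, int W, int B) {
  const int C = A.n_rows;
  const size_t HW = (size_t)H * W;
  const mat At = A.t();  // (HWB x C): contiguous reads per channel
  mat Pt(HW * B, 9 * C, fill::zeros);
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy) {
      for (int c = 0; c < C; ++c) {
        double* col = Pt.colptr(c + C * (dy + 3 * dx));
        const double* src = At.colptr(c);
        for (int b = 0; b < B; ++b) {
          const size_t base = HW * b;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx - 1;
            if (sw < 0 || sw >= W) continue;
            const int h0 = std::max(0, 1 - dy);
            const int h1 = std::min(H, H + 1 - dy);
            double* dst = col + base + (size_t)H * w + h0;
            const double* sp = src + base + (size_t)H * sw + (h0 + dy - 1);
            std::copy(sp, sp + (h1 - h0), dst);
          }
        }
      }
    }
  }
  return Pt;
}

// [[Rcpp::export]]
arma::mat cpp_im2col3x3(const arma::mat& A, int H, int W, int B) {
  return im2col3x3_t(A, H, W, B);
}

// out = Wmat %*% t(Pt) + bias, with Pt a patch matrix from cpp_im2col3x3
// [[Rcpp::export]]
arma::mat cpp_conv_patches(const arma::mat& Pt, const arma::mat& Wmat,
                           const arma::vec& bias) {
  mat out = Wmat * Pt.t();
  out.each_col() += bias;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_conv3x3_fwd(const arma::mat& A, const arma::mat& Wmat,
                          const arma::vec& bias, int H, int W, int B) {
  return cpp_conv_patches(im2col3x3_t(A, H, W, B), Wmat, bias);
}

// weight/bias gradients from the cached patch matrix; the data gradient
// is computed in R as a forward convolution with the flipped kernel
// [[Rcpp::export]]
Rcpp::List cpp_conv3x3_wgrad(const arma::mat& Pt, const arma::mat& dOut) {
  mat dW = dOut * Pt;
  vec db = sum(dOut, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::mat& A, int H, int W, int B) {
  const int C = A.n_rows;
  const int H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  mat out(C, HW2 * B);
  umat amax(C, HW2 * B);  // 0-based linear column index into A
  for (int b = 0; b < B; ++b) {
    for (int w2 = 0; w2 < W2; ++w2) {
      for (int h2 = 0; h2 < H2; ++h2) {
        const size_t o = HW2 * b + (size_t)H2 * w2 + h2;
        const size_t s00 = HW * b + (size_t)H * (2 * w2) + 2 * h2;
        const size_t cand[4] = {s00, s00 + 1, s00 + H, s00 + H + 1};
        for (int c = 0; c < C; ++c) {
          double best = A(c, cand[0]);
          size_t bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            if (A(c, cand[k]) > best) { best = A(c, cand[k]); bi = cand[k]; }
          }
          out(c, o) = best;
          amax(c, o) = bi;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("amax") = amax);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dOut, const arma::umat& amax,
                          int C, size_t in_cols) {
  mat dA(C, in_cols, fill::zeros);
  for (size_t j = 0; j < dOut.n_cols; ++j) {
    for (int c = 0; c < C; ++c) {
      dA(c, amax(c, j)) += dOut(c, j);
    }
  }
  return dA;
}

// per-channel mean and biased variance over all columns
// [[Rcpp::export]]
Rcpp::List cpp_row_stats(const arma::mat& A) {
  vec mu = mean(A, 1);
  vec m2 = mean(square(A), 1);
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = m2 - square(mu));
}

// fused out = relu(gamma * (A - mu) * inv + beta)
// [[Rcpp::export]]
arma::mat cpp_bnrelu_fwd(const arma::mat& A, const arma::vec& gamma,
                         const arma::vec& beta, const arma::vec& mu,
                         const arma::vec& inv) {
  const int C = A.n_rows;
  const size_t n = A.n_cols;
  mat out(C, n);
  for (size_t j = 0; j < n; ++j) {
    const double* a = A.colptr(j);
    double* o = out.colptr(j);
    for (int c = 0; c < C; ++c) {
      double v = gamma[c] * (a[c] - mu[c]) * inv[c] + beta[c];
      o[c] = v > 0 ? v : 0;
    }
  }
  return out;
}

// fused backward through ReLU (mask from the forward output) and batch
// normalization (batch statistics mu, inv); returns dA, dgamma, dbeta
// [[Rcpp::export]]
Rcpp::List cpp_bnrelu_bwd(const arma::mat& dOut, const arma::mat& A,
                          const arma::mat& out, const arma::vec& gamma,
                          const arma::vec& mu, const arma::vec& inv) {
  const int C = A.n_rows;
  const size_t n = A.n_cols;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  mat dR(C, n);
  for (size_t j = 0; j < n; ++j) {
    const double* dp = dOut.colptr(j);
    const double* op = out.colptr(j);
    const double* ap = A.colptr(j);
    double* rp = dR.colptr(j);
    for (int c = 0; c < C; ++c) {
      double g = op[c] > 0 ? dp[c] : 0.0;
      rp[c] = g;
      dbeta[c] += g;
      dgamma[c] += g * (ap[c] - mu[c]) * inv[c];
    }
  }
  mat dA(C, n);
  for (size_t j = 0; j < n; ++j) {
    const double* rp = dR.colptr(j);
    const double* ap = A.colptr(j);
    double* da = dA.colptr(j);
    for (int c = 0; c < C; ++c) {
      double xhat = (ap[c] - mu[c]) * inv[c];
      da[c] = gamma[c] * inv[c] *
        (rp[c] - dbeta[c] / n - xhat * (dgamma[c] / n));
    }
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
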
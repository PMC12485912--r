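// Hot loops of the surrogate trunk: dilated 1-d convolution (zero-padded,
// odd kernels) over B stacked individual blocks, tanh-approximation GELU,
// and within-trunk average pooling. Rows of X are individual-major:
// row = i*L + p. W is (k*Cin) x Cout with tap-major blocks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// shifted copy of X into the tap-major im2col buffer: column (j*Cin + c)
// of Col is column c of X shifted by off_j, zero outside each block
static void im2col_fill(const mat& X, mat& Col, int B, int L, int k, int d) {
  const int Cin = X.n_cols;
  for (int j = 0; j < k; ++j) {
    const int off = d * (j - (k - 1) / 2);
    const int t0 = std::max(0, -off), t1 = std::min(L - 1, L - 1 - off);
    for (int c = 0; c < Cin; ++c) {
      double* dst = Col.colptr(j * Cin + c);
      const double* src = X.colptr(c);
      std::fill(dst, dst + B * L, 0.0);
      if (t0 > t1) continue;
      for (int i = 0; i < B; ++i)
        std::copy(src + i * L + t0 + off, src + i * L + t1 + 1 + off,
                  dst + i * L + t0);
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& W,
                       const arma::rowvec& b, int B, int L, int k, int d) {
  mat Col(B * L, k * X.n_cols);
  im2col_fill(X, Col, B, L, k, d);
  mat Z = Col * W;
  Z.each_row() += b;
  return Z;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
Rcpp::List cpp_conv_bwd(const arma::mat& X, const arma::mat& dZ,
                        const arma::mat& W, int B, int L, int k, int d,
                        bool need_dx) {
  const int Cin = X.n_cols;
  mat Col(B * L, k * Cin);
  im2col_fill(X, Col, B, L, k, d);
  mat dW = Col.t() * dZ;
  mat dX;
  if (need_dx) {
    mat dCol = dZ * W.t();
    dX.zeros(X.n_rows, Cin);
    // scatter-add each tap block back with the opposite shift
    for (int j = 0; j < k; ++j) {
      const int off = d * (j - (k - 1) / 2);
      const int t0 = std::max(0, -off), t1 = std::min(L - 1, L - 1 - off);
      if (t0 > t1) continue;
      for (int c = 0; c < Cin; ++c) {
        const double* src = dCol.colptr(j * Cin + c);
        double* dst = dX.colptr(c);
        for (int i = 0; i < B; ++i) {
          const double* s = src + i * L + t0;
          double* t = dst + i * L + t0 + off;
          const int nrun = t1 - t0 + 1;
          for (int r = 0; r < nrun; ++r) t[r] += s[r];
        }
      }
    }
  }
  rowvec db = sum(dZ, 0);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

static inline double gelu_tanh(double z, double* grad) {
  const double c1 = 0.7978845608028654;   // sqrt(2/pi)
  const double c2 = 0.044715;
  const double u = c1 * (z + c2 * z * z * z);
  const double t = std::tanh(u);
  if (grad)
    *grad = 0.5 * (1.0 + t) +
            0.5 * z * (1.0 - t * t) * c1 * (1.0 + 3.0 * c2 * z * z);
  return 0.5 * z * (1.0 + t);
}

// [[Rcpp::export(name = ".cpp_gelu_fwd")]]
arma::mat cpp_gelu_fwd(const arma::mat& Z) {
  mat A(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  double* a = A.memptr();
  const size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i) a[i] = gelu_tanh(z[i], nullptr);
  return A;
}

// [[Rcpp::export(name = ".cpp_gelu_bwd")]]
arma::mat cpp_gelu_bwd(const arma::mat& Z, const arma::mat& dA) {
  mat dZ(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  const double* da = dA.memptr();
  double* dz = dZ.memptr();
  const size_t n = Z.n_elem;
  double g;
  for (size_t i = 0; i < n; ++i) {
    gelu_tanh(z[i], &g);
    dz[i] = da[i] * g;
  }
  return dZ;
}

// [[Rcpp::export(name = ".cpp_avgpool_fwd")]]
arma::mat cpp_avgpool_fwd(const arma::mat& A, int w) {
  const int n = A.n_rows / w, C = A.n_cols;
  mat P(n, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int g = 0; g < n; ++g) {
      double s = 0;
      for (int r = 0; r < w; ++r) s += A(g * w + r, c);
      P(g, c) = s / w;
    }
  return P;
}

// [[Rcpp::export(name = ".cpp_avgpool_bwd")]]
arma::mat cpp_avgpool_bwd(const arma::mat& dP, int w) {
  const int n = dP.n_rows, C = dP.n_cols;
  mat dA(n * w, C);
  for (int c = 0; c < C; ++c)
    for (int g = 0; g < n; ++g) {
      const double v = dP(g, c) / w;
      for (int r = 0; r < w; ++r) dA(g * w + r, c) = v;
    }
  return dA;
}
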
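// Low-level dense kernels for the counting network: im2col convolution
// (arbitrary dilation, zero padding, stride 1) and 2x2 max-pooling, with
// the exact adjoints used by backpropagation. Feature maps are (H, W, C)
// cubes in R's column-major layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_dim(int n, int k, int pad, int dil) {
  return n + 2 * pad - (dil * (k - 1) + 1) + 1;
}

static mat im2col(const cube& x, int k, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, pad, dil), Wo = out_dim(W, k, pad, dil);
  mat cols(k * k * C, (size_t)Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + kj * k + c * k * k;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j + kj * dil - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i + ki * dil - pad;
            if (xi < 0 || xi >= H) continue;
            cols(row, (size_t)i + (size_t)j * Ho) = xs(xi, xj);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int H, int W, int C, int k, int pad, int dil) {
  const int Ho = out_dim(H, k, pad, dil), Wo = out_dim(W, k, pad, dil);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + kj * k + c * k * k;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j + kj * dil - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i + ki * dil - pad;
            if (xi < 0 || xi >= H) continue;
            xs(xi, xj) += cols(row, (size_t)i + (size_t)j * Ho);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b, int k, int pad, int dil) {
  const int Ho = out_dim(x.n_rows, k, pad, dil), Wo = out_dim(x.n_cols, k, pad, dil);
  mat cols = im2col(x, k, pad, dil);
  mat out = W * cols;           // (Cout, Ho*Wo)
  out.each_col() += b;
  cube y(Ho, Wo, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    y.slice(c) = reshape(out.row(c), Ho, Wo);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& x, const arma::mat& W,
                             const arma::cube& dout, int k, int pad, int dil) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  mat dmat(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dmat.row(c) = vectorise(dout.slice(c)).t();
  mat cols = im2col(x, k, pad, dil);
  mat dW = dmat * cols.t();
  vec db = sum(dmat, 1);
  mat dcols = W.t() * dmat;
  cube dx = col2im(dcols, x.n_rows, x.n_cols, x.n_slices, k, pad, dil);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C); // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = xs(i0, j0);
        uword bi = i0 + (uword)j0 * H;
        // fixed 2x2 window; first maximum wins ties (deterministic)
        if (xs(i0 + 1, j0) > best) { best = xs(i0 + 1, j0); bi = (i0 + 1) + (uword)j0 * H; }
        if (xs(i0, j0 + 1) > best) { best = xs(i0, j0 + 1); bi = i0 + (uword)(j0 + 1) * H; }
        if (xs(i0 + 1, j0 + 1) > best) { best = xs(i0 + 1, j0 + 1); bi = (i0 + 1) + (uword)(j0 + 1) * H; }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::ucube& idx, const arma::cube& dy,
                                int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxs = dx.slice(c);
    const mat& dys = dy.slice(c);
    const umat& is = idx.slice(c);
    for (uword n = 0; n < dys.n_elem; ++n)
      dxs(is(n)) += dys(n);
  }
  return dx;
}
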
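// Dense compute kernels for the segmentation network: same-padding 3x3/1x1
// convolution via im2col + GEMM, ceil-mode 2x2 max pooling, and strided
// transposed convolution. Tensors are H x W x C cubes; convolution weights
// are (kh*kw*Cin) x Cout matrices with row index c*kh*kw + ki*kw + kj.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col(const cube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat out(H * W, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int ki = 0; ki < kh; ++ki) {
      const int r0 = std::max(0, ph - ki);
      const int r1 = std::min(H, H + ph - ki);
      if (r1 <= r0) continue;
      for (int kj = 0; kj < kw; ++kj) {
        const int col = c * kh * kw + ki * kw + kj;
        const int c0 = std::max(0, pw - kj);
        const int c1 = std::min(W, W + pw - kj);
        double* dst = out.colptr(col);
        for (int j = c0; j < c1; ++j) {
          const double* src = sl.colptr(j + kj - pw) + (r0 + ki - ph);
          std::memcpy(dst + (size_t)j * H + r0, src,
                      (size_t)(r1 - r0) * sizeof(double));
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int kh, const int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = x.slice(c);
    for (int ki = 0; ki < kh; ++ki) {
      const int r0 = std::max(0, ph - ki);
      const int r1 = std::min(H, H + ph - ki);
      if (r1 <= r0) continue;
      for (int kj = 0; kj < kw; ++kj) {
        const int col = c * kh * kw + ki * kw + kj;
        const int c0 = std::max(0, pw - kj);
        const int c1 = std::min(W, W + pw - kj);
        const double* src = cols.colptr(col);
        for (int j = c0; j < c1; ++j) {
          double* dst = sl.colptr(j + kj - pw) + (r0 + ki - ph);
          const double* s = src + (size_t)j * H + r0;
          for (int i = 0; i < r1 - r0; ++i) dst[i] += s[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col(x, kh, kw);
  mat out = cols * w;
  out.each_row() += b.t();
  cube y(H, W, Cout);
  std::memcpy(y.memptr(), out.memptr(), out.n_elem * sizeof(double));
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  mat dyMat(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  mat cols = im2col(x, kh, kw);
  mat dW = cols.t() * dyMat;
  vec db = sum(dyMat, 0).t();
  mat dCols = dyMat * w.t();
  cube dx = col2im(dCols, H, W, C, kh, kw);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// ceil-mode 2x2 max pooling, stride 2; idx records the argmax linear index
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  cube y(Ho, Wo, C);
  umat idx(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          const int jj = 2 * j + dj;
          if (jj >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di;
            if (ii >= H) continue;
            const double v = sl(ii, jj);
            if (v > best) { best = v; bi = ii + (uword)jj * H; }
          }
        }
        y(i, j, c) = best;
        idx(i + (uword)j * Ho, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const arma::umat& idx,
                        const int H, const int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = dy.slice(c).memptr();
    double* d = dx.slice(c).memptr();
    for (int k = 0; k < Ho * Wo; ++k) d[idx(k, c)] += g[k];
  }
  return dx;
}

// transposed convolution, stride s, k x k kernel; full (uncropped) output
// of size (H-1)*s + k. Weights: 4-d array (k, k, Cin, Cout).
// [[Rcpp::export]]
arma::cube convtr2d_fwd(const arma::cube& x, const Rcpp::NumericVector& w,
                        const arma::vec& b, const int k, const int s) {
  Rcpp::IntegerVector dims = w.attr("dim");
  const int Cin = dims[2], Cout = dims[3];
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H - 1) * s + k, Wo = (W - 1) * s + k;
  const double* wp = w.begin();
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co) {
    mat& out = y.slice(co);
    for (int ci = 0; ci < Cin; ++ci) {
      const mat& in = x.slice(ci);
      const double* wk = wp + ((size_t)co * Cin + ci) * k * k;
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const double v = in(i, j);
          if (v == 0.0) continue;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              out(i * s + ki, j * s + kj) += v * wk[ki + kj * k];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List convtr2d_bwd(const arma::cube& x, const Rcpp::NumericVector& w,
                        const arma::cube& dy, const int k, const int s) {
  Rcpp::IntegerVector dims = w.attr("dim");
  const int Cin = dims[2], Cout = dims[3];
  const int H = x.n_rows, W = x.n_cols;
  const double* wp = w.begin();
  cube dx(H, W, Cin, fill::zeros);
  Rcpp::NumericVector dW(w.size());
  dW.attr("dim") = dims;
  double* dwp = dW.begin();
  vec db(Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const mat& g = dy.slice(co);
    db(co) = accu(g);
    for (int ci = 0; ci < Cin; ++ci) {
      const mat& in = x.slice(ci);
      mat& dxs = dx.slice(ci);
      const double* wk = wp + ((size_t)co * Cin + ci) * k * k;
      double* dwk = dwp + ((size_t)co * Cin + ci) * k * k;
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const double v = in(i, j);
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
              const double gij = g(i * s + ki, j * s + kj);
              acc += gij * wk[ki + kj * k];
              dwk[ki + kj * k] += v * gij;
            }
          }
          dxs(i, j) += acc;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
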